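test_that("generator produces the configured gene census, deterministically", {
  cfg <- cluster_config(seed = 42L, n_sedc = 5L, n_sftp = 2L,
                        lce_array_size = 10L, lesion_rate = 0)
  cl <- generate_cluster(cfg)
  g <- cl$truth$genes
  expect_equal(nrow(g), 5 + 2 + 10 + 2)
  expect_equal(sum(g$family != "anchor"), 17)
  expect_equal(sum(g$family == "SFTP"), 2)
  expect_equal(sum(g$family == "LCE-like"), 10)
  expect_true(all(c("+", "-") %in% g$strand))
  expect_true(all(g$status == "intact"))

  cl2 <- generate_cluster(cfg)
  expect_identical(cl$sequence, cl2$sequence)
  expect_identical(cl$truth, cl2$truth)

  # genes are ordered and non-overlapping
  expect_true(all(diff(g$start) > 0))
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
})

test_that("gene units have the stated architectures and canonical introns", {
  cl <- tiny_cluster()
  ex <- cl$truth$exons
  g <- cl$truth$genes
  for (gene in g$gene) {
    e <- ex[ex$gene == gene, ]
    n_coding <- sum(e$coding)
    fam <- g$family[g$gene == gene]
    expect_equal(n_coding, if (fam == "SFTP") 2L else 1L, info = gene)
    # canonical GT..AG introns on the sense strand
    u <- cl$templates[[gene]]
    ue <- u$exons[order(u$exons$start), ]
    for (i in seq_len(nrow(ue) - 1)) {
      intr <- substr(u$dna, ue$end[i] + 1, ue$start[i + 1])
      expect_identical(substr(intr, 1, 2), "GT", info = gene)
      expect_identical(substr(intr, nchar(intr) - 1, nchar(intr)), "AG",
                       info = gene)
    }
    # CDS translates to the template protein without internal stops
    expect_false(grepl("\\*", u$protein))
    expect_equal(nchar(u$cds) %% 3, 0)
  }
})

test_that("implanted lesions are real at the sequence level", {
  cl <- tiny_cluster()
  get_cds <- function(cl, gene) {
    g <- cl$truth$genes[cl$truth$genes$gene == gene, ]
    e <- cl$truth$exons[cl$truth$exons$gene == gene & cl$truth$exons$coding, ]
    s <- paste(vapply(seq_len(nrow(e)), function(i) {
      substr(cl$sequence, e$start[i] + 1, e$end[i])
    }, ""), collapse = "")
    if (g$strand == "-") reverse_complement(s) else s
  }
  # premature stop: '*' appears exactly at the recorded codon
  m1 <- implant_lesion(cl, "SEDC2", "premature_stop", position = 30)
  p <- translate_dna(get_cds(m1, "SEDC2"), 0, "+")
  expect_identical(substr(p, 30, 30), "*")
  expect_identical(m1$truth$genes$status[m1$truth$genes$gene == "SEDC2"],
                   "truncated")

  # frameshift deletion: CDS length mod 3 changes accordingly
  m2 <- implant_lesion(cl, "SEDC3", "frameshift_del")
  k <- as.integer(sub("del", "", m2$lesions$detail[1]))
  expect_true(k %in% 1:2)
  expect_equal(nchar(get_cds(m2, "SEDC3")) %% 3, (3 - k) %% 3)
  expect_identical(m2$truth$genes$status[m2$truth$genes$gene == "SEDC3"],
                   "pseudogene")

  # exon deletion: scaffold shrinks by the deleted (sense-order second
  # coding) exon's length
  u <- cl$templates[["SFTP1"]]
  cod <- u$exons[u$exons$coding, ]
  m3 <- implant_lesion(cl, "SFTP1", "exon_deletion", position = 2)
  expect_equal(nchar(cl$sequence) - nchar(m3$sequence),
               cod$end[2] - cod$start[2])

  # splice loss: the donor/acceptor dinucleotide is no longer canonical
  m4 <- implant_lesion(cl, "SEDC1", "splice_loss")
  u <- m4$templates[["SEDC1"]]
  g <- m4$truth$genes[m4$truth$genes$gene == "SEDC1", ]
  ex4 <- m4$truth$exons[m4$truth$exons$gene == "SEDC1", ]
  ex4 <- ex4[order(ex4$start), ]
  intr <- substr(m4$sequence, ex4$end[1] + 1, ex4$start[2])
  if (g$strand == "-") intr <- reverse_complement(intr)
  expect_false(substr(intr, 1, 2) == "GT" &&
                 substr(intr, nchar(intr) - 1, nchar(intr)) == "AG")
})

test_that("truth invariants hold on lesioned clusters across seeds", {
  for (seed in c(7L, 19L)) {
    cl <- generate_cluster(cluster_config(seed = seed, n_sedc = 8L,
                                          n_sftp = 3L, lce_array_size = 4L,
                                          lesion_rate = 0.5))
    g <- cl$truth$genes
    les <- cl$lesions
    # no lesions <=> intact
    for (gene in g$gene) {
      has <- gene %in% les$gene
      expect_identical(g$status[g$gene == gene] == "intact", !has)
    }
    # lesion coordinates fall inside the gene span
    for (i in seq_len(nrow(les))) {
      row <- g[g$gene == les$gene[i], ]
      expect_gte(les$genomic_pos[i], row$start)
      expect_lt(les$genomic_pos[i], row$end)
    }
    # status recomputation from truth lesions matches the stored status
    for (gene in unique(les$gene)) {
      tc <- nchar(cl$templates[[gene]]$protein) + 1L
      expect_identical(
        classify_status(les[les$gene == gene, ], tc),
        g$status[g$gene == gene])
    }
  }
})

test_that("tandem amplification obeys its contracts", {
  founder <- rand_dna(300, 11)
  # single copy: array equals founder, genealogy a single leaf
  a1 <- amplify_tandem(founder, 1, 0, seed = 1)
  expect_identical(a1$sequence, founder)
  expect_identical(a1$tree, "copy1")
  # zero divergence: all copies identical
  a2 <- amplify_tandem(founder, 5, 0, seed = 2)
  expect_true(all(a2$copies == founder))
  # determinism
  a3 <- amplify_tandem(founder, 6, 0.05, seed = 3)
  a3b <- amplify_tandem(founder, 6, 0.05, seed = 3)
  expect_identical(a3$copies, a3b$copies)
  expect_identical(ape::write.tree(a3$tree), ape::write.tree(a3b$tree))
  # genealogy is ultrametric in duplication-event count
  expect_true(ape::is.ultrametric(a3$tree))
  # with outgroups, the copies form a monophyletic clade in the genealogy
  ogs <- stats::setNames(vapply(1:3, function(i) {
    withr::with_seed(i, edcscan:::.mutate_dna(founder, 0.3))
  }, ""), paste0("og", 1:3))
  a4 <- amplify_tandem(founder, 8, 0.02, seed = 4, outgroups = ogs)
  expect_true(as.logical(is_monophyletic(a4$tree, a4$copy_labels, "og1")))
})

test_that("oversized configurations are refused", {
  cfg <- cluster_config(seed = 1L, n_sedc = 3000L, n_sftp = 500L,
                        lce_array_size = 3000L, intergenic_mean = 2000L)
  expect_error(generate_cluster(cfg), "10 Mbp")
})

test_that("write_cluster emits the complete text bundle", {
  cl <- tiny_cluster()
  dir <- withr::local_tempdir()
  write_cluster(cl, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "scaffold.fa", "truth.gff3", "truth_genes.tsv", "truth_lesions.tsv",
    "template_proteins.faa", "lce_genealogy.nwk", "config.json")))))
  fa <- read_fasta(file.path(dir, "scaffold.fa"))
  expect_identical(unname(fa[1]), cl$sequence)
})
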