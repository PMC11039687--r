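test_that("family counting between anchors partitions by status", {
  cl <- tiny_cluster()
  anchors <- cl$config$anchor_names
  ct <- count_family_in_window(cl$truth, "LCE-like", anchors[1], anchors[2])
  expect_equal(unname(ct["functional"]), 3)
  expect_equal(unname(ct["pseudogene"]), 0)
  # absent family
  expect_equal(unname(count_family_in_window(cl$truth, "nope", anchors[1],
                                             anchors[2])["functional"]), 0)
  # lesioned copies move to the pseudogene column
  m <- implant_lesion(cl, "LCE1", "frameshift_del")
  ct2 <- count_family_in_window(m$truth, "LCE-like", anchors[1], anchors[2])
  expect_equal(unname(ct2["functional"]), 2)
  expect_equal(unname(ct2["pseudogene"]), 1)
  # anchors on different scaffolds are refused
  broken <- cl$truth
  broken$genes$scaffold[broken$genes$gene == anchors[2]] <- "other"
  expect_error(count_family_in_window(broken, "SEDC", anchors[1], anchors[2]),
               "different scaffolds")
})

test_that("family matrix cells sum to the per-species gene tally", {
  cl <- tiny_cluster()
  anchors <- cl$config$anchor_names
  fm <- family_matrix(list(speciesA = cl$truth), anchors)
  counts <- attr(fm, "counts")
  expect_equal(sum(counts), sum(cl$truth$genes$family != "anchor"))
})

test_that("the pipeline reproduces a lesion-free sister cluster exactly", {
  ref <- tiny_cluster()
  tgt <- tiny_sister()
  rep <- run_pipeline(ref, tgt, seed = 1L)
  tg <- tgt$truth$genes
  ra <- rep$annotation$genes
  expect_setequal(ra$gene, tg$gene)
  m <- match(tg$gene, ra$gene)
  expect_identical(ra$architecture[m], tg$architecture)
  expect_true(all(ra$status == "intact"))
  expect_equal(sum(vapply(rep$disruptions,
                          function(d) nrow(d$lesions), 0L)), 0)
  expect_true(all(rep$orthology$verdict == "ortholog"))
  # reconstructed family counts equal the truth counts
  anchors <- ref$config$anchor_names
  fm_rec <- attr(family_matrix(list(t = rep$annotation), anchors), "counts")
  fm_tru <- attr(family_matrix(list(t = tgt$truth), anchors), "counts")
  expect_equal(fm_rec, fm_tru)
})

test_that("a stop + frameshift gene is reported as pseudogene in the matrix", {
  ref <- tiny_cluster()
  tgt <- tiny_sister()
  tgt <- implant_lesion(tgt, "SEDC4", "premature_stop", position = 5)
  tgt <- implant_lesion(tgt, "SEDC4", "frameshift_ins")
  rep <- run_pipeline(ref, tgt, seed = 1L)
  expect_identical(rep$disruptions[["SEDC4"]]$status, "pseudogene")
  anchors <- ref$config$anchor_names
  counts <- attr(rep$family_matrix, "counts")
  expect_equal(unname(counts["SEDC", "target", "pseudogene"]), 1)
})

test_that("a missing anchor aborts the run with its name", {
  ref <- tiny_cluster()
  expect_error(run_pipeline(ref, c(chr = rand_dna(20000, 701))),
               ref$config$anchor_names[1])
})

test_that("report writing and the manifest make reruns reproducible", {
  ref <- tiny_cluster()
  tgt <- tiny_sister()
  r1 <- run_pipeline(ref, tgt, seed = 9L)
  r2 <- run_pipeline(ref, tgt, seed = 9L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_report(r1, d1)
  write_report(r2, d2)
  for (f in c("annotation.gff3", "genes.tsv", "proteins.faa",
              "orthology.tsv", "lesions.tsv", "composition.tsv",
              "motifs.tsv", "family_matrix.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_identical(r1$manifest$target_md5, r2$manifest$target_md5)
})

test_that("the CLI drives simulate, search and tree end to end", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "sim")
  expect_message(
    edc_scan_cli(c("simulate", "--seed", "5", "--out", out,
                   "--n-sedc", "2", "--n-sftp", "1", "--lce", "2")),
    "synthetic cluster")
  expect_true(file.exists(file.path(out, "scaffold.fa")))
  hits <- file.path(dir, "hits.tsv")
  expect_message(
    edc_scan_cli(c("search", "--query",
                   file.path(out, "template_proteins.faa"),
                   "--genome", file.path(out, "scaffold.fa"),
                   "--out", hits)),
    "HSPs")
  expect_gt(nrow(utils::read.delim(hits)), 0)
  nwk <- file.path(dir, "tree.nwk")
  expect_message(
    edc_scan_cli(c("tree", "--proteins",
                   file.path(out, "template_proteins.faa"),
                   "--bootstrap", "10", "--seed", "3", "--out", nwk)),
    "NJ tree")
  tr <- ape::read.tree(nwk)
  expect_s3_class(tr, "phylo")
})
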