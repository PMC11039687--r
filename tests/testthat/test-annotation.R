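# helper to fabricate an hsp_table row
mk_hsp <- function(qstart, qend, gstart, gend, score = 100, strand = "+",
                   frame = 0L, scaffold = "s1", query = "q") {
  structure(data.frame(
    query_id = query, scaffold_id = scaffold, strand = strand,
    frame = frame, qstart = qstart, qend = qend, gstart = gstart,
    gend = gend, score = score, pident = 100, alen = qend - qstart + 1L,
    qaln = "", taln = "", stringsAsFactors = FALSE),
    class = c("hsp_table", "data.frame"))
}

test_that("HSP chaining respects collinearity and the intron bound", {
  h <- rbind(mk_hsp(1, 50, 1000, 1150), mk_hsp(51, 100, 1650, 1800))
  # 500 bp apart, collinear -> one locus
  expect_length(chain_hsps(h, max_intron = 10000), 1)
  # same pair under a 100 bp bound -> two loci
  expect_length(chain_hsps(h, max_intron = 100), 2)
  # inverted query order -> collinearity violated -> two loci
  h2 <- rbind(mk_hsp(51, 100, 1000, 1150), mk_hsp(1, 50, 1650, 1800))
  expect_length(chain_hsps(h2, max_intron = 10000), 2)
  # minus strand: transcription order runs right to left
  h3 <- rbind(mk_hsp(1, 50, 1650, 1800, strand = "-"),
              mk_hsp(51, 100, 1000, 1150, strand = "-"))
  expect_length(chain_hsps(h3, max_intron = 10000), 1)
})

test_that("template-guided models recover intact synthetic genes exactly", {
  cl <- tiny_cluster()
  scaf <- stats::setNames(cl$sequence, cl$scaffold_id)
  idx <- six_frame_index(scaf)
  for (g in cl$truth$genes$gene) {
    h <- search_translated(
      stats::setNames(cl$templates[[g]]$protein, g), idx)
    loci <- chain_hsps(h)
    m <- build_gene_model(loci[[1]], cl$templates[[g]], scaf)
    tex <- cl$truth$exons[cl$truth$exons$gene == g, ]
    tex <- tex[order(tex$start), ]
    expect_equal(m$exons$start, tex$start, info = g)
    expect_equal(m$exons$end, tex$end, info = g)
    expect_identical(m$source, "template_guided")
    # translated model reproduces the query protein
    expect_identical(m$protein, cl$templates[[g]]$protein, info = g)
    expect_identical(
      m$architecture,
      cl$truth$genes$architecture[cl$truth$genes$gene == g], info = g)
  }
})

test_that("a mutated splice site fails boundary refinement with a flag", {
  cl <- tiny_cluster()
  mut <- implant_lesion(cl, "SEDC2", "splice_loss")
  scaf <- stats::setNames(mut$sequence, mut$scaffold_id)
  h <- search_translated(
    stats::setNames(mut$templates[["SEDC2"]]$protein, "SEDC2"), scaf)
  loci <- chain_hsps(h)
  m <- build_gene_model(loci[[1]], mut$templates[["SEDC2"]], scaf)
  expect_true(any(grepl("splice_unresolved", m$flags)))
  expect_identical(m$architecture, "other")  # flagged models are not classified
})

test_that("architecture classification follows the coding-exon rules", {
  cl <- tiny_cluster()
  # single coding exon -> SEDC
  sedc <- exon_template(cl$templates[["SEDC1"]])
  m1 <- list(exons = sedc$exons, protein = sedc$protein, strand = "+")
  expect_identical(classify_architecture(m1), "SEDC")
  # two coding exons with an N-terminal S100 consensus hit -> SFTP
  sftp <- exon_template(cl$templates[["SFTP1"]])
  m2 <- list(exons = sftp$exons, protein = sftp$protein, strand = "+")
  expect_identical(classify_architecture(m2), "SFTP")
  # two coding exons without the domain -> other
  fake <- m2
  fake$protein <- rand_protein(nchar(sftp$protein), 61)
  expect_identical(classify_architecture(fake), "other")
  # three coding exons -> other
  ex3 <- rbind(sftp$exons,
               data.frame(start = max(sftp$exons$end) + 100,
                          end = max(sftp$exons$end) + 200,
                          coding = TRUE, phase = 0L))
  expect_identical(classify_architecture(list(exons = ex3,
                                              protein = sftp$protein,
                                              strand = "+")), "other")
})

test_that("the S100 profile separates domain carriers from background", {
  prof <- s100_profile()
  dom <- withr::with_seed(71, edcscan:::.mutate_protein(s100_consensus(), 0.1))
  hit <- edcscan:::.profile_score(dom, prof)
  expect_gte(hit, 0.6 * prof$self_score)
  bg <- rand_protein(200, 72)
  expect_lt(edcscan:::.profile_score(bg, prof), 0.6 * prof$self_score)
})
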