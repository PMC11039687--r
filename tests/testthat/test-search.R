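test_that("low-complexity masking follows entropy with an explicit off switch", {
  # off switch returns input untouched
  expect_identical(mask_low_complexity("QQQQQQQQQQQQ", enabled = FALSE),
                   "QQQQQQQQQQQQ")
  # homopolymer window: entropy 0 bits, fully masked
  expect_identical(mask_low_complexity("QQQQQQQQQQQQ", window = 12,
                                       entropy_threshold = 2.2),
                   "qqqqqqqqqqqq")
  # 12 distinct residues: entropy log2(12) = 3.58 bits, unmasked
  div <- "ACDEFGHIKLMN"
  expect_identical(mask_low_complexity(div, window = 12,
                                       entropy_threshold = 2.2), div)
  # poly-QP: 1 bit per window, masked
  qp <- strrep("QP", 20)
  expect_identical(mask_low_complexity(qp), tolower(qp))
})

test_that("translated search recovers an embedded exon exactly", {
  prot <- rand_protein(60, 31)
  cds <- withr::with_seed(32, edcscan:::.rev_translate(prot))
  genome <- paste0(rand_dna(5000, 33), cds, rand_dna(5000, 34))
  h <- search_translated(c(q = prot), c(scf = genome))
  expect_gt(nrow(h), 0)
  top <- h[which.max(h$score), ]
  expect_equal(top$pident, 100)
  expect_equal(top$gstart, 5000)
  expect_equal(top$gend, 5180)
  expect_identical(top$strand, "+")
  expect_equal(top$qstart, 1)
  expect_equal(top$qend, 60)

  # strand symmetry: reverse-complementing the scaffold flips the strand
  # and mirrors coordinates, nothing else
  h2 <- search_translated(c(q = prot), c(scf = reverse_complement(genome)))
  top2 <- h2[which.max(h2$score), ]
  expect_identical(top2$strand, "-")
  expect_equal(top2$gstart, nchar(genome) - 5180)
  expect_equal(top2$gend, nchar(genome) - 5000)
  expect_equal(top2$score, top$score)
})

test_that("every reported HSP score is reproducible from its alignment", {
  cl <- tiny_cluster()
  prots <- vapply(cl$templates[1:6], `[[`, "", "protein")
  h <- search_translated(prots, stats::setNames(cl$sequence, cl$scaffold_id))
  expect_gt(nrow(h), 5)
  for (i in seq_len(nrow(h))) {
    expect_equal(hsp_score(h$qaln[i], h$taln[i]), h$score[i],
                 info = sprintf("row %d", i))
  }
  # BLOSUM62 diagonal check: an exact MKV alignment scores 5 + 5 + 4
  expect_equal(hsp_score("MKV", "MKV"), 14)
})

test_that("masking changes search results exactly as designed", {
  # a repeat-rich (poly-QP, loricrin-like) protein hidden in random DNA
  qp <- strrep("QP", 30)
  cds <- withr::with_seed(41, edcscan:::.rev_translate(qp))
  genome <- paste0(rand_dna(4000, 42), cds, rand_dna(4000, 43))
  unmasked <- search_translated(c(q = qp), c(scf = genome))
  expect_gt(nrow(unmasked), 0)
  expect_equal(unmasked$gstart[1], 4000)
  masked <- search_translated(c(q = mask_low_complexity(qp)),
                              c(scf = genome))
  expect_equal(nrow(masked), 0)
  # an ordinary query is unaffected by masking
  prot <- rand_protein(80, 44)
  expect_identical(mask_low_complexity(prot), prot)
})

test_that("hit tables serialize to 1-based BLAST-like TSV", {
  prot <- rand_protein(50, 51)
  cds <- withr::with_seed(52, edcscan:::.rev_translate(prot))
  genome <- paste0(rand_dna(1000, 53), cds, rand_dna(1000, 54))
  h <- search_translated(c(q = prot), c(scf = genome))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, path)
  tab <- utils::read.delim(path)
  expect_equal(tab$sstart[1], h$gstart[1] + 1)
  expect_equal(tab$send[1], h$gend[1])
})
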