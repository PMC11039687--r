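test_that("amino-acid composition is exact and normalized", {
  cp <- aa_composition("RRREEE")
  expect_equal(unname(cp$freq["R"]), 0.5)
  expect_equal(unname(cp$freq["E"]), 0.5)
  expect_equal(cp$top2_fraction, 1.0)
  expect_equal(unname(aa_composition("G")$freq["G"]), 1.0)
  for (seed in 1:3) {
    p <- rand_protein(150, seed)
    expect_equal(sum(aa_composition(p)$freq), 1, tolerance = 1e-9)
  }
  # X is excluded from the denominator
  cpx <- aa_composition("GGXX")
  expect_equal(unname(cpx$freq["G"]), 1.0)
  expect_error(aa_composition(""), "empty")
})

test_that("repeat detection matches exact and near-exact arrays", {
  r <- detect_repeats("GSQGSQGSQ", min_unit = 3)
  expect_equal(nrow(r), 1)
  expect_equal(r$unit_len, 3)
  expect_equal(r$copies, 3)
  expect_identical(r$consensus, "GSQ")
  expect_equal(r$identity, 1)

  r2 <- detect_repeats("GSQGSQGAQ", min_unit = 3)
  expect_equal(r2$unit_len, 3)
  expect_identical(r2$consensus, "GSQ")
  expect_equal(r2$identity, 8 / 9)
})

test_that("random proteins rarely trigger repeat calls", {
  hits <- vapply(1:200, function(seed) {
    nrow(detect_repeats(rand_protein(200, 7000 + seed),
                        min_unit = 3, min_copies = 3,
                        min_identity = 0.8)) > 0
  }, TRUE)
  expect_lte(mean(hits), 0.05)
})

test_that("repeat detection recovers the generator's SFTP tail unit", {
  cl <- tiny_cluster()
  for (g in c("SFTP1", "SFTP2")) {
    u <- cl$templates[[g]]
    r <- detect_repeats(u$protein, min_unit = 5, max_unit = 30,
                        min_copies = 3, min_identity = 0.7)
    expect_gt(nrow(r), 0)
    best <- r[which.max((r$end - r$start) * r$identity), ]
    # exact unit length, or resolved to it from an integer multiple
    expect_equal(best$unit_len, u$repeat_unit_len, info = g)
    # the array lies in the tail, after the S100 domain
    expect_gt(best$start, 85)
  }
})

test_that("composition of biased synthetic tails matches the configured bias", {
  cl <- tiny_cluster()
  for (g in c("SFTP1", "SFTP2")) {
    u <- cl$templates[[g]]
    # the repeat region: after the S100-like domain, before the motif
    tail_prot <- substr(u$protein, 92,
                        nchar(u$protein) - nchar(sftp_cterm_motif()))
    cp <- aa_composition(tail_prot)
    # generator: 78% of tail-unit residues drawn from the two bias letters
    # (per-copy substitution erodes this slightly)
    expect_setequal(cp$top2, u$tail_bias)
    expect_lt(abs(cp$top2_fraction - 0.78), 0.05)
  }
})

test_that("C-terminal motif scanning respects the window rule", {
  motif <- sftp_cterm_motif()
  p1 <- paste0(rand_protein(120, 201), motif)
  m1 <- scan_cterminal_motif(p1, motif)
  expect_true(m1$found)
  expect_equal(m1$distance_from_cterm, 0)
  expect_equal(m1$score, 1)
  # absent everywhere
  m2 <- scan_cterminal_motif(rand_protein(100, 202), "WWWWWWWW")
  expect_false(m2$found)
  # present only at the N-terminus, outside the window
  p3 <- paste0(motif, rand_protein(120, 203))
  expect_false(scan_cterminal_motif(p3, motif, window = 50)$found)
  # wildcards count as matches
  m4 <- scan_cterminal_motif(p1, paste0(substr(motif, 1, 6), "xx"))
  expect_true(m4$found)
  # the generator appends the motif to every intact SFTP protein
  cl <- tiny_cluster()
  for (g in c("SFTP1", "SFTP2")) {
    expect_true(scan_cterminal_motif(cl$templates[[g]]$protein, motif)$found,
                info = g)
  }
})

test_that("segment architecture splits around the repeat region", {
  rep <- data.frame(unit_len = 10, start = 21, end = 80, copies = 6,
                    consensus = "x", identity = 1)
  p <- strrep("A", 100)
  s <- segment_architecture(p, rep)
  expect_equal(s$n_term, c(1, 20))
  expect_equal(s$repeat_region, c(21, 80))
  expect_equal(s$c_term, c(81, 100))
  # repeats to the last residue: empty C-terminal segment
  rep2 <- rep; rep2$end <- 100
  expect_true(all(is.na(segment_architecture(p, rep2)$c_term)))
  # repeats from the first residue: empty N-terminal segment
  rep3 <- rep; rep3$start <- 1
  expect_true(all(is.na(segment_architecture(p, rep3)$n_term)))
  # no repeats: whole protein as N-terminal, flagged
  s4 <- segment_architecture(p, rep[0, ])
  expect_true(attr(s4, "flagged"))
  expect_equal(s4$n_term, c(1, 100))
})
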