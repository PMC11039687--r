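test_that("implanted lesions are detected with exact kind and coordinate", {
  cl <- tiny_cluster()
  scaf <- function(x) stats::setNames(x$sequence, x$scaffold_id)
  reg <- function(x, g) x$truth$genes[x$truth$genes$gene == g, ]

  # premature stop at a chosen codon
  m <- implant_lesion(cl, "SEDC1", "premature_stop", position = 50)
  r <- detect_disruptions(scaf(m), reg(m, "SEDC1"), m$templates[["SEDC1"]],
                          margin = 50)
  expect_equal(nrow(r$lesions), 1)
  expect_identical(r$lesions$kind, "premature_stop")
  expect_equal(r$lesions$codon_index, 50)
  expect_equal(r$lesions$genomic_pos, m$lesions$genomic_pos[1])

  # 1-2 bp deletion -> one frameshift at the recorded position
  m <- implant_lesion(cl, "SFTP2", "frameshift_del")
  r <- detect_disruptions(scaf(m), reg(m, "SFTP2"), m$templates[["SFTP2"]],
                          margin = 50)
  fs <- r$lesions[r$lesions$kind == "frameshift", ]
  expect_equal(nrow(fs), 1)
  expect_equal(fs$genomic_pos, m$lesions$genomic_pos[1])

  # unmutated gene: zero lesions, intact
  r <- detect_disruptions(scaf(cl), reg(cl, "SEDC3"),
                          cl$templates[["SEDC3"]], margin = 50)
  expect_equal(nrow(r$lesions), 0)
  expect_identical(r$status, "intact")
  expect_equal(r$longest_orf_fraction, 1)
})

test_that("stop + frameshift in distinct exons classifies as pseudogene", {
  cl <- tiny_cluster()
  # caspase-14-like case: a premature stop in one coding exon and a
  # frameshift in another
  m <- implant_lesion(cl, "SFTP1", "premature_stop", position = 40)
  cds_len <- nchar(m$templates[["SFTP1"]]$cds)
  m <- implant_lesion(m, "SFTP1", "frameshift_del", position = 300)
  r <- detect_disruptions(stats::setNames(m$sequence, m$scaffold_id),
                          m$truth$genes[m$truth$genes$gene == "SFTP1", ],
                          m$templates[["SFTP1"]], margin = 50)
  expect_setequal(r$lesions$kind, c("premature_stop", "frameshift"))
  expect_identical(r$status, "pseudogene")
})

test_that("status classification follows the stated rules", {
  none <- data.frame(gene = character(0), kind = character(0),
                     genomic_pos = integer(0), codon_index = integer(0),
                     detail = character(0))
  expect_identical(classify_status(none, 300), "intact")
  stop40 <- data.frame(gene = "g", kind = "premature_stop",
                       genomic_pos = 1L, codon_index = 120L, detail = "TAA")
  expect_identical(classify_status(stop40, 300), "truncated")  # 40% runway
  stop_early <- stop40; stop_early$codon_index <- 10L
  expect_identical(classify_status(stop_early, 300), "pseudogene")  # < 20%
  fs_then_stop <- rbind(
    data.frame(gene = "g", kind = "frameshift", genomic_pos = 1L,
               codon_index = 50L, detail = "del1"), stop40)
  expect_identical(classify_status(fs_then_stop, 300), "pseudogene")
  splice <- data.frame(gene = "g", kind = "splice_loss", genomic_pos = 1L,
                       codon_index = NA_integer_, detail = "donor")
  expect_identical(classify_status(splice, 300), "pseudogene")
})

test_that("ORF runway counting matches its examples and a closed-form oracle", {
  r <- measure_orf_runway("AAAAAATAA", 0, "+")
  expect_equal(r$codons, 2)
  expect_equal(r$stop_pos, 6)
  expect_equal(measure_orf_runway("TAACCC", 0, "+")$codons, 0)
  r2 <- measure_orf_runway("AAATTATTT", 8, "-")  # revcomp from the end
  expect_equal(r2$codons, 1)

  # oracle: stop-codon start positions per frame, runway by lookup
  seq <- rand_dna(3000, 101)
  stops <- which(vapply(seq_len(nchar(seq) - 2),
                        function(i) substr(seq, i, i + 2) %in%
                          edcscan:::.STOPS, TRUE))  # 1-based starts
  for (pos in withr::with_seed(102, sample(0:(nchar(seq) - 3), 200))) {
    frame_stops <- stops[(stops - 1) %% 3 == pos %% 3 & (stops - 1) >= pos]
    got <- measure_orf_runway(seq, pos, "+")
    if (length(frame_stops)) {
      expect_equal(got$codons, (frame_stops[1] - 1 - pos) / 3)
      expect_equal(got$stop_pos, frame_stops[1] - 1)
    } else {
      expect_true(got$hit_end)
    }
  }
  # mean runway over random sequence approximates 64/3 codons
  runs <- vapply(withr::with_seed(103, sample(0:(nchar(seq) - 3), 400)),
                 function(p) measure_orf_runway(seq, p, "+")$codons, 0)
  expect_lt(abs(mean(runs) - 64 / 3), 6)
})

test_that("shortening fraction is clipped arithmetic", {
  expect_equal(shortening_fraction(100, 400), 0.75)
  expect_equal(shortening_fraction(400, 400), 0)
  longer <- shortening_fraction(500, 400)
  expect_equal(as.numeric(longer), 0)
  expect_identical(attr(longer, "flag"), "target_longer")
})

test_that("degenerate loci produce a missing-exon pseudogene report", {
  cl <- tiny_cluster()
  g <- cl$truth$genes[cl$truth$genes$gene == "SFTP1", ]
  tiny_region <- list(scaffold_id = g$scaffold, start = g$start,
                      end = g$start + 20L, strand = g$strand)
  r <- detect_disruptions(stats::setNames(cl$sequence, cl$scaffold_id),
                          tiny_region, cl$templates[["SFTP1"]])
  expect_identical(r$status, "pseudogene")
  expect_true(all(r$lesions$kind == "missing_exon"))
  expect_identical(r$flags, "locus_too_short")
})
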