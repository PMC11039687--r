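test_that("p-distances use pairwise deletion and are symmetric", {
  aln <- c(a = "AAAA", b = "AATT", c = "AAAA")
  D <- pdistance_matrix(aln)
  expect_equal(D["a", "b"], 0.5)
  expect_equal(D["a", "c"], 0)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  # gapped positions are excluded pairwise
  aln2 <- c(a = "A-AA", b = "AATA", c = "AAAA")
  expect_equal(pdistance_matrix(aln2)["a", "b"], 1 / 3)
  # fully gapped pair errors with the pair named
  aln3 <- c(a = "--AA", b = "AA--", c = "AAAA")
  expect_error(pdistance_matrix(aln3), "'a' and 'b'")
})

test_that("neighbor joining resolves the additive four-taxon case", {
  D <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(D)
  expect_identical(edcscan:::.splits(tr), "A|B")  # the AB|CD split
  # n = 3: unique star topology with closed-form branch lengths
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- neighbor_joining(D3)
  bl <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 1, 3))
  # label-invariance: permuting rows leaves the topology unchanged
  perm <- c("C", "A", "D", "B")
  tr2 <- neighbor_joining(D[perm, perm])
  expect_setequal(edcscan:::.splits(tr2), edcscan:::.splits(tr))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|square")
})

test_that("NJ recovers random additive trees exactly (ape as cross-check)", {
  ok_mine <- ok_ape <- 0
  for (i in 1:40) {
    t0 <- withr::with_seed(400 + i, {
      n <- sample(5:8, 1)
      ape::unroot(ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2)))
    })
    D <- stats::cophenetic(t0)
    tr <- neighbor_joining(D)
    ok_mine <- ok_mine + setequal(edcscan:::.splits(tr), edcscan:::.splits(t0))
    # independent route: ape's own NJ agrees with ours
    ok_ape <- ok_ape + setequal(edcscan:::.splits(ape::nj(D)),
                                edcscan:::.splits(tr))
  }
  expect_equal(ok_mine, 40)
  expect_equal(ok_ape, 40)
})

test_that("monophyly is judged on the outgroup-rooted tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(as.logical(is_monophyletic(tr, c("A", "B"), "D")))
  expect_false(as.logical(is_monophyletic(tr, c("A", "C"), "D")))
  m <- is_monophyletic(tr, "A", "D")  # singleton: trivially a clade
  expect_true(as.logical(m))
  expect_true(attr(m, "trivial"))
  full <- is_monophyletic(tr, c("A", "B", "C"), "D")
  expect_true(attr(full, "trivial"))
  expect_error(is_monophyletic(tr, c("A", "D"), "D"), "outgroup")
})

test_that("bootstrap supports are deterministic and flag degenerate input", {
  founder <- rand_dna(300, 501)
  ogs <- stats::setNames(vapply(1:3, function(i) {
    withr::with_seed(510 + i, edcscan:::.mutate_dna(founder, 0.3))
  }, ""), paste0("og", 1:3))
  amp <- amplify_tandem(founder, 6, 0.02, seed = 502, outgroups = ogs)
  aligned <- c(amp$copies, ogs)
  b1 <- bootstrap_support(aligned, 50, seed = 7)
  b2 <- bootstrap_support(aligned, 50, seed = 7)
  expect_identical(b1$supports, b2$supports)
  expect_gt(clade_support(b1, amp$copy_labels), 50)
  # identical sequences: no informative sites, flagged
  same <- c(x = "AAAA", y = "AAAA", z = "AAAA")
  expect_true(bootstrap_support(same, 5, seed = 1)$degenerate)
})

test_that("progressive alignment restores comparability of unequal rows", {
  seqs <- c(a = "MKVLINTAGE", b = "MKVINTAGE", c = "MKVLINTAGEQ")
  aln <- progressive_align(seqs)
  expect_length(unique(nchar(aln)), 1)
  # ungapped content is preserved
  expect_identical(gsub("-", "", aln[["a"]]), seqs[["a"]])
  expect_identical(gsub("-", "", aln[["b"]]), seqs[["b"]])
  D <- pdistance_matrix(aln)
  expect_lt(D["a", "b"], 0.2)
})

test_that("the true genealogy of an amplified array is always monophyletic", {
  founder <- rand_dna(240, 601)
  for (i in 1:10) {
    ogs <- c(og = withr::with_seed(610 + i,
                                   edcscan:::.mutate_dna(founder, 0.3)))
    amp <- amplify_tandem(founder, 5, 0.05, seed = 620 + i, outgroups = ogs)
    expect_true(as.logical(is_monophyletic(amp$tree, amp$copy_labels, "og")))
  }
})
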