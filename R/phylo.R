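# Distance-based gene-family phylogenetics: p-distances with pairwise
# deletion, an in-package neighbor-joining implementation (Saitou-Nei,
# deterministic lowest-index tie rule), nonparametric bootstrap supports
# and a rooted monophyly test. Trees are ape "phylo" objects throughout.

#' Pairwise p-distance matrix of aligned sequences
#'
#' Entry (i, j) is mismatches / compared positions, where positions with a
#' gap (`-`) in either row are excluded (pairwise deletion).
#'
#' @param aligned Named character vector of equal-length aligned rows
#'   (DNA or protein), or a character matrix (rows = sequences).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(aligned) {
  mat <- if (is.matrix(aligned)) aligned else {
    .check(length(unique(nchar(aligned))) == 1L,
           "aligned sequences must have equal length")
    do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  }
  if (is.null(rownames(mat))) rownames(mat) <- names(aligned)
  n <- nrow(mat)
  .check(n >= 3L, "need at least 3 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    if (!any(ok)) {
      stop(sprintf("no comparable positions between '%s' and '%s'",
                   rownames(mat)[i], rownames(mat)[j]), call. = FALSE)
    }
    D[i, j] <- D[j, i] <- mean(mat[i, ok] != mat[j, ok])
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. The Q-matrix minimum is resolved to
#' the lowest index pair for determinism; negative branch lengths are
#' clamped to zero (flagged via the `clamped` attribute).
#'
#' @param D Symmetric distance matrix with at least 3 labelled rows.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  .check(is.matrix(D) && nrow(D) == ncol(D), "D must be square")
  .check(max(abs(D - t(D))) < 1e-12, "D must be symmetric")
  n <- nrow(D)
  .check(n >= 3L, "need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels  # newick fragments of active nodes
  clamped <- FALSE
  cl <- function(x) { if (x < 0) { clamped <<- TRUE; 0 } else x }
  while (length(nodes) > 3L) {
    m <- length(nodes)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- cl(D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2)))
    lj <- cl(D[i, j] - li)
    lj <- cl(lj)
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nodes[i], li, nodes[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], new_nwk)
    rownames(D) <- colnames(D) <- NULL
  }
  # terminal 3-star: closed-form branch lengths
  l1 <- cl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- cl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- cl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nodes[1], l1, nodes[2], l2, nodes[3], l3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Test whether a label set is monophyletic relative to an outgroup
#'
#' The tree is rooted on the outgroup; the set is monophyletic iff the
#' clade under the most recent common ancestor of the set contains exactly
#' the set.
#'
#' @param tree An `ape::phylo`.
#' @param labels Character vector of tip labels (the putative clade).
#' @param outgroup A tip label not in `labels` to root on.
#' @return Logical; attributes `node` (the supporting MRCA node id in the
#'   rooted tree when TRUE) and `trivial` (TRUE when `labels` covers all
#'   non-outgroup tips, or is a singleton).
#' @export
is_monophyletic <- function(tree, labels, outgroup) {
  .check(all(c(labels, outgroup) %in% tree$tip.label),
         "labels must be tips of the tree")
  .check(!outgroup %in% labels, "outgroup must not be in the label set")
  if (length(labels) == 1L) {
    return(structure(TRUE, node = which(tree$tip.label == labels),
                    trivial = TRUE))
  }
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  mrca <- ape::getMRCA(rt, labels)
  tips <- ape::extract.clade(rt, mrca)$tip.label
  ok <- setequal(tips, labels)
  trivial <- setequal(labels, setdiff(tree$tip.label, outgroup))
  structure(ok, node = if (ok) mrca else NA_integer_, trivial = trivial)
}

# canonical keys of the non-trivial bipartitions (splits) of an unrooted
# tree: each internal edge -> sorted tip subset containing tip 1
.splits <- function(tree) {
  n <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  out <- character(0)
  post <- ape::prop.part(tree)  # tip sets under each internal node
  for (p in post) {
    tips <- sort(tree$tip.label[p])
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    if (!(all_tips[1] %in% tips)) tips <- setdiff(all_tips, tips)
    if (length(tips) <= 1L || length(tips) >= n - 1L) next
    out <- c(out, paste(sort(tips), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the full-data tree with
#' the percentage of replicates containing its bipartition. Deterministic
#' given `seed`.
#'
#' @param aligned Named character vector of equal-length aligned rows.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List of class `edc_bootstrap`: `tree` (full-data NJ tree with
#'   `node.label` supports), `supports` (split key -> percentage),
#'   `n_replicates`, `seed`, `degenerate` flag (no variable columns).
#' @export
bootstrap_support <- function(aligned, n_replicates = 100L, seed = 1L) {
  .check(n_replicates >= 1L, "need at least one replicate")
  mat <- do.call(rbind, strsplit(aligned, "", fixed = TRUE))
  rownames(mat) <- names(aligned)
  ncol_a <- ncol(mat)
  degenerate <- all(apply(mat, 2, function(col) length(unique(col)) == 1L))
  full <- neighbor_joining(pdistance_matrix(mat))
  want <- .splits(full)
  counts <- stats::setNames(numeric(length(want)), want)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
      Dr <- tryCatch(pdistance_matrix(mat[, cols, drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(Dr)) next
      sp <- .splits(neighbor_joining(Dr))
      hit <- want %in% sp
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- 100 * counts / n_replicates
  # annotate node labels of the full tree
  full$node.label <- rep("", full$Nnode)
  pp <- ape::prop.part(full)
  n <- length(full$tip.label)
  all_tips <- sort(full$tip.label)
  for (k in seq_along(pp)) {
    tips <- sort(full$tip.label[pp[[k]]])
    if (!(all_tips[1] %in% tips)) tips <- setdiff(all_tips, tips)
    key <- paste(sort(tips), collapse = "|")
    if (key %in% names(supports)) {
      full$node.label[k] <- sprintf("%.0f", supports[key])
    }
  }
  structure(list(tree = full, supports = supports,
                 n_replicates = n_replicates, seed = seed,
                 degenerate = degenerate),
            class = "edc_bootstrap")
}

#' @export
print.edc_bootstrap <- function(x, ...) {
  cat(sprintf("edc_bootstrap: %d tips, %d replicates (seed %d)%s\n",
              length(x$tree$tip.label), x$n_replicates, x$seed,
              if (x$degenerate) " [degenerate: no variable sites]" else ""))
  if (length(x$supports)) {
    cat("split supports (%):\n")
    for (k in names(x$supports)) cat(sprintf("  %5.1f  %s\n", x$supports[k], k))
  }
  invisible(x)
}

#' Bootstrap support of one clade
#'
#' @param bs An `edc_bootstrap`.
#' @param labels Tip labels of the clade.
#' @return The support percentage of the bipartition separating `labels`
#'   from the rest, or NA if that split is not in the full-data tree.
#' @export
clade_support <- function(bs, labels) {
  all_tips <- sort(bs$tree$tip.label)
  tips <- sort(labels)
  if (!(all_tips[1] %in% tips)) tips <- setdiff(all_tips, tips)
  key <- paste(sort(tips), collapse = "|")
  if (key %in% names(bs$supports)) unname(bs$supports[key]) else NA_real_
}

#' Progressive multiple alignment of protein or DNA sequences
#'
#' Simple center-star progressive alignment over pairwise global
#' alignments (Biostrings): every sequence is aligned to the longest
#' sequence and gaps are projected into a common coordinate frame. This
#' is internal plumbing for tree building on sequences of unequal length;
#' equal-length inputs are returned unchanged.
#'
#' @param seqs Named character vector.
#' @param type "protein" or "dna".
#' @return Named character vector of equal-length aligned rows.
#' @export
progressive_align <- function(seqs, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (length(unique(nchar(seqs))) == 1L) return(seqs)
  M <- if (type == "protein") .blosum62() else .dna_submat()
  center <- names(seqs)[which.max(nchar(seqs))]
  others <- setdiff(names(seqs), center)
  # per-sequence alignment to the center; collect insertion points
  alns <- lapply(others, function(id) {
    a <- Biostrings::pairwiseAlignment(
      seqs[[id]], seqs[[center]], type = "global",
      substitutionMatrix = M, gapOpening = 10, gapExtension = 1)
    list(q = strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1]],
         s = strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1]])
  })
  names(alns) <- others
  # how many inserted columns each alignment needs after each center pos
  clen <- nchar(seqs[[center]])
  ins_need <- matrix(0L, length(others), clen + 1L,
                     dimnames = list(others, NULL))
  for (id in others) {
    s <- alns[[id]]$s
    pos <- cumsum(s != "-")          # center position per column
    gaps <- s == "-"
    if (any(gaps)) {
      tab <- table(pos[gaps])
      ins_need[id, as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
  }
  ins <- apply(ins_need, 2, max)
  # rebuild every row in the master frame
  build <- function(qch, sch) {
    out <- character(0)
    cpos <- 0L
    pend_ins <- character(0)
    flush <- function(k) c(pend_ins, rep("-", k - length(pend_ins)))
    for (col in seq_along(sch)) {
      if (sch[col] == "-") {
        pend_ins <- c(pend_ins, qch[col])
      } else {
        out <- c(out, flush(ins[cpos + 1L]))
        pend_ins <- character(0)
        out <- c(out, qch[col])
        cpos <- cpos + 1L
      }
    }
    out <- c(out, flush(ins[cpos + 1L]))
    paste(out, collapse = "")
  }
  center_ch <- strsplit(seqs[[center]], "", fixed = TRUE)[[1]]
  res <- stats::setNames(character(length(seqs)), names(seqs))
  res[center] <- build(center_ch, center_ch)
  for (id in others) res[id] <- build(alns[[id]]$q, alns[[id]]$s)
  res
}
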