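# Orthology calling by the two criteria used throughout cluster-level
# comparative work: reciprocal best hits between protein sets and shared
# local synteny of the flanking gene-family neighborhood.

# local-alignment score matrix between two protein sets (BLOSUM62,
# affine gaps); Smith-Waterman local scores are symmetric in the pair
.protein_score_matrix <- function(a, b, gap_open = 11, gap_extend = 1) {
  M <- .blosum62()
  out <- matrix(0, length(a), length(b), dimnames = list(names(a), names(b)))
  aset <- Biostrings::AAStringSet(unlist(a))
  for (j in seq_along(b)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      aset, b[[j]], type = "local", substitutionMatrix = M,
      gapOpening = gap_open, gapExtension = gap_extend,
      scoreOnly = TRUE)
  }
  out
}

#' Reciprocal-best-hit test for one protein
#'
#' TRUE iff `a`'s best hit in `proteome_b`, searched back against
#' `proteome_a`, returns `a` as the unique best hit. A tie for best score
#' in either direction returns FALSE with attribute `ambiguous = TRUE`.
#'
#' @param a Name of the query protein in `proteome_a`.
#' @param proteome_a,proteome_b Named character vectors of proteins.
#' @return Logical flag with attributes `best_b` (the forward best hit)
#'   and `ambiguous`.
#' @export
reciprocal_best_hit <- function(a, proteome_a, proteome_b) {
  .check(a %in% names(proteome_a), "query not in proteome_a")
  .check(length(proteome_b) > 0L && length(proteome_a) > 0L,
         "empty proteome")
  m <- .protein_score_matrix(proteome_a[a], proteome_b)
  fwd <- stats::setNames(as.vector(m), colnames(m))
  top <- max(fwd)
  if (sum(fwd == top) > 1L) {
    return(structure(FALSE, best_b = names(which(fwd == top)),
                     best_score = top, ambiguous = TRUE))
  }
  b <- names(which.max(fwd))
  m2 <- .protein_score_matrix(proteome_b[b], proteome_a)
  back <- stats::setNames(as.vector(m2), colnames(m2))
  topb <- max(back)
  if (sum(back == topb) > 1L) {
    return(structure(FALSE, best_b = b, best_score = top, ambiguous = TRUE))
  }
  structure(names(which.max(back)) == a, best_b = b, best_score = top,
            ambiguous = FALSE)
}

# flanking families of a gene: up to k annotated genes on each side of the
# locus on its scaffold, in coordinate order
.flank_families <- function(ann, gene, k) {
  g <- ann$genes
  row <- g[g$gene == gene, ]
  .check(nrow(row) == 1L, sprintf("gene '%s' not in annotation", gene))
  same <- g[g$scaffold == row$scaffold, , drop = FALSE]
  same <- same[order(same$start), , drop = FALSE]
  i <- which(same$gene == gene)
  left <- same$family[seq_len(i - 1L)]
  right <- same$family[seq.int(i + 1L, length.out = nrow(same) - i)]
  fams <- c(utils::tail(left, k), utils::head(right, k))
  flagged <- length(fams) < 2L * k
  structure(fams, flagged = flagged)
}

#' Shared-local-synteny score between two loci
#'
#' The fraction of the up-to-`2k` genes flanking `gene_a` (k per side)
#' whose gene family also occurs among the families flanking `gene_b`;
#' order-insensitive. Fewer than `2k` available flanks are used as-is and
#' flagged.
#'
#' @param ann_a,ann_b `edc_annotation` objects containing the two loci.
#' @param gene_a,gene_b Gene names.
#' @param k Flanking genes per side.
#' @return Fraction in [0, 1]; attribute `flagged` when flanks were short.
#' @export
synteny_score <- function(ann_a, gene_a, ann_b, gene_b, k = 3L) {
  fa <- .flank_families(ann_a, gene_a, k)
  fb <- .flank_families(ann_b, gene_b, k)
  if (!length(fa)) return(structure(0, flagged = TRUE))
  structure(mean(fa %in% fb),
            flagged = attr(fa, "flagged") || attr(fb, "flagged"))
}

#' Call orthology for one gene, or a whole annotated proteome
#'
#' `call_ortholog()` applies the criteria of comparative cluster analysis:
#' verdict "ortholog" requires a reciprocal best hit and synteny at or
#' above `synteny_threshold`; "ambiguous" is a failed RBH (e.g. a tie
#' among near-identical tandem copies) with conserved synteny; "none"
#' otherwise. `call_orthologs()` loops over every gene of the reference
#' annotation and returns the calls as a data frame.
#'
#' @param gene Query gene name in the reference annotation.
#' @param ref,target Lists with `ann` (an `edc_annotation`) and `proteins`
#'   (named character vector, same gene names).
#' @param k Flanking genes per side for synteny.
#' @param synteny_threshold Minimum synteny fraction.
#' @return One-row (or per-gene) data frame: query, target, rbh,
#'   ambiguous, synteny, verdict.
#' @export
call_ortholog <- function(gene, ref, target, k = 3L,
                          synteny_threshold = 0.5) {
  .check(length(target$proteins) > 0L, "target annotation is empty")
  rbh <- reciprocal_best_hit(gene, ref$proteins, target$proteins)
  best <- attr(rbh, "best_b")[1]
  syn <- if (best %in% target$ann$genes$gene) {
    as.numeric(synteny_score(ref$ann, gene, target$ann, best, k))
  } else 0
  # a failed RBH only qualifies as a candidate paralog/pseudo-ortholog when
  # the forward hit is close to the query's self-score; a weak best hit
  # (the true ortholog deleted, some paralog surfacing) is "none"
  self <- .protein_score_matrix(ref$proteins[gene], ref$proteins[gene])[1, 1]
  strong <- attr(rbh, "best_score") >= 0.5 * self
  verdict <- if (isTRUE(as.logical(rbh)) && syn >= synteny_threshold) {
    "ortholog"
  } else if (strong && syn >= synteny_threshold) "ambiguous" else "none"
  data.frame(query = gene, target = best, rbh = as.logical(rbh),
             ambiguous = isTRUE(attr(rbh, "ambiguous")), synteny = syn,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' @rdname call_ortholog
#' @export
call_orthologs <- function(ref, target, k = 3L, synteny_threshold = 0.5) {
  out <- do.call(rbind, lapply(ref$ann$genes$gene, function(g) {
    call_ortholog(g, ref, target, k, synteny_threshold)
  }))
  rownames(out) <- NULL
  out
}
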