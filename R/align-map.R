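# DNA-level alignment of an intact template gene against a locus region,
# with a coordinate map between the two. Uses Biostrings::pairwiseAlignment
# with BLASTN-like scoring; indel blocks can be left-normalized so that
# lesion coordinates are canonical.

.dna_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = FALSE)
    }
    m
  }
})

# Globally align template DNA (pattern, fully aligned) into a region
# (subject, local). Returns per-column parallel vectors:
#   tpos: 0-based template position of the column (NA for gap)
#   rpos: 0-based region/target position of the column (NA for gap)
# plus the aligned character vectors and the subject offset.
.align_map <- function(template_dna, region_dna, gap_open = 6, gap_extend = 1) {
  aln <- Biostrings::pairwiseAlignment(
    template_dna, region_dna, type = "global-local",
    substitutionMatrix = .dna_submat(),
    gapOpening = gap_open, gapExtension = gap_extend)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ta <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based region offset
  tpos <- ifelse(qa != "-", cumsum(qa != "-") - 1L, NA_integer_)
  rpos <- ifelse(ta != "-", s0 + cumsum(ta != "-") - 1L, NA_integer_)
  list(qa = qa, ta = ta, tpos = tpos, rpos = rpos,
       score = as.numeric(Biostrings::score(aln)))
}

# For each 0-based template position, the 0-based target position it aligns
# to (NA where the template base is deleted in the target).
.template_to_target <- function(map, template_len) {
  out <- rep(NA_integer_, template_len)
  ok <- !is.na(map$tpos) & !is.na(map$rpos)
  out[map$tpos[ok] + 1L] <- map$rpos[ok]
  out
}

# Indel runs of the alignment as a data frame:
#   type: "ins" (extra target bases) or "del" (missing template bases)
#   tpl: 0-based template position of the run (for ins: position before
#        which the block sits; for del: first deleted template base)
#   trg: 0-based target position (for ins: first inserted base; for del:
#        the junction, i.e. target bases before the gap)
#   len: run length
.indel_runs <- function(map) {
  gap_q <- map$qa == "-"   # insertion in target
  gap_t <- map$ta == "-"   # deletion from template
  runs <- list()
  r <- rle(gap_q)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    a <- starts[i]; b <- ends[i]
    tpl_after <- map$tpos[which(!gap_q & seq_along(gap_q) > b)][1]
    tpl <- if (is.na(tpl_after)) max(map$tpos, na.rm = TRUE) + 1L else tpl_after
    runs[[length(runs) + 1L]] <- data.frame(
      type = "ins", tpl = tpl, trg = map$rpos[a], len = b - a + 1L)
  }
  r <- rle(gap_t)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    a <- starts[i]; b <- ends[i]
    prev_trg <- map$rpos[which(!gap_t & seq_along(gap_t) < a)]
    junction <- if (length(prev_trg)) prev_trg[length(prev_trg)] + 1L else {
      rp <- map$rpos[!is.na(map$rpos)]
      if (length(rp)) rp[1] else 0L
    }
    runs[[length(runs) + 1L]] <- data.frame(
      type = "del", tpl = map$tpos[a], trg = junction, len = b - a + 1L)
  }
  if (!length(runs)) {
    return(data.frame(type = character(0), tpl = integer(0),
                      trg = integer(0), len = integer(0)))
  }
  out <- do.call(rbind, runs)
  out[order(out$tpl, out$type), , drop = FALSE]
}

# left-normalize an indel run against template/target sense sequences,
# returning updated (tpl, trg); mirrors the truth convention of the
# generator.
.normalize_run <- function(run, template_dna, target_dna) {
  k <- run$len
  if (run$type == "ins") {
    a <- .normalize_indel_left(target_dna, run$trg, k)
    shift <- run$trg - a
    list(tpl = run$tpl - shift, trg = a)
  } else {
    a <- .normalize_indel_left(template_dna, run$tpl, k)
    shift <- run$tpl - a
    list(tpl = a, trg = run$trg - shift)
  }
}
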