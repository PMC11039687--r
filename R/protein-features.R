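# Protein feature profiling: amino-acid composition (the computation
# behind ProtParam-style content tables), internal tandem repeat
# detection, C-terminal motif scanning and N-terminal / repeat /
# C-terminal segment architecture.

#' Amino-acid composition of a protein
#'
#' Exact per-residue frequencies over the 20-letter alphabet; X is allowed
#' but excluded from the denominator. The combined fraction of the two
#' most frequent residues summarizes composition bias (repeat-rich EDC
#' proteins can reach ~50% from just two residues).
#'
#' @param protein Protein string.
#' @param id Optional identifier carried in the result.
#' @return A `composition_profile`: id, length, freq (named numeric,
#'   sums to 1), top2 (names) and top2_fraction.
#' @export
aa_composition <- function(protein, id = "protein") {
  .check(is.character(protein) && nzchar(protein), "empty protein")
  aa <- setdiff(names(.aa_codons()), "*")
  ch <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  ch <- ch[ch != "X" & ch != "*"]
  .check(length(ch) > 0L, "protein has no countable residues")
  .check(all(ch %in% aa), "protein contains non-standard residues")
  f <- tabulate(factor(ch, levels = aa), nbins = length(aa))
  freq <- stats::setNames(f / length(ch), aa)
  ord <- order(-freq)
  structure(list(id = id, length = length(ch), freq = freq,
                 top2 = aa[ord[1:2]],
                 top2_fraction = sum(freq[ord[1:2]])),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("composition_profile %s: %d aa; top2 %s+%s = %.1f%%\n",
              x$id, x$length, x$top2[1], x$top2[2], 100 * x$top2_fraction))
  invisible(x)
}

#' Detect internal tandem repeats in a protein
#'
#' For each candidate unit length the sequence is compared with itself at
#' that lag; maximal high-identity runs are reported as repeat arrays with
#' a column-majority consensus. Overlapping calls are resolved to the
#' highest copy-number x identity; unit-length ambiguity (u vs 2u) is
#' resolved to the smallest unit whose identity is within 2 points of the
#' best. X residues count as mismatches.
#'
#' @param protein Protein string.
#' @param min_unit,max_unit Candidate unit lengths (residues).
#' @param min_copies Minimum copies (span/unit) to report.
#' @param min_identity Minimum lag-match fraction over the array span.
#' @return A data frame (possibly empty): unit_len, start, end (1-based
#'   inclusive residue span), copies, consensus, identity (mean
#'   copy-to-consensus fraction).
#' @export
detect_repeats <- function(protein, min_unit = 3L, max_unit = 30L,
                           min_copies = 3L, min_identity = 0.8) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cand <- list()
  for (u in seq.int(min_unit, min(max_unit, n %/% max(min_copies, 2L)))) {
    m <- ch[seq_len(n - u)] == ch[(u + 1L):n] & ch[seq_len(n - u)] != "X"
    # maximal runs with overall lag-identity >= min_identity: greedy
    # extension from each match run start
    i <- 1L
    while (i <= length(m)) {
      if (!m[i]) { i <- i + 1L; next }
      j <- i; matches <- 0L; best_j <- i - 1L
      while (j <= length(m)) {
        matches <- matches + m[j]
        if (matches / (j - i + 1L) >= min_identity) best_j <- j
        if ((j - best_j) > u) break  # too long a mismatch stretch; stop
        j <- j + 1L
      }
      span_lag <- best_j - i + 1L
      span <- span_lag + u           # residues covered incl. final copy
      if (span >= u * min_copies) {
        seg <- ch[i:(i + span - 1L)]
        ncp <- span / u
        cols <- split(seg, (seq_along(seg) - 1L) %% u)
        consensus <- vapply(cols, function(col) {
          names(sort(table(col), decreasing = TRUE))[1]
        }, "")
        cons_rep <- rep_len(consensus, span)
        ident <- mean(seg == cons_rep)
        cand[[length(cand) + 1L]] <- data.frame(
          unit_len = u, start = i, end = i + span - 1L, copies = ncp,
          consensus = paste(consensus, collapse = ""), identity = ident,
          stringsAsFactors = FALSE)
      }
      i <- max(i + 1L, best_j + u + 1L)
    }
  }
  if (!length(cand)) {
    return(data.frame(unit_len = integer(0), start = integer(0),
                      end = integer(0), copies = numeric(0),
                      consensus = character(0), identity = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  # resolve overlaps: best copy-number x identity wins; prefer the
  # smallest unit within 2 identity points (u vs 2u ambiguity)
  cand$score <- cand$copies * cand$identity
  cand <- cand[order(-cand$score, cand$unit_len), , drop = FALSE]
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i, ]
    clash <- FALSE
    for (kk in kept) {
      ov <- min(ci$end, kk$end) - max(ci$start, kk$start) + 1L
      if (ov > 0.5 * min(ci$end - ci$start, kk$end - kk$start)) {
        # same array: keep the kept one unless ci has a smaller unit at
        # near-equal identity and is an integer divisor
        clash <- TRUE
        break
      }
    }
    if (!clash) kept[[length(kept) + 1L]] <- ci
  }
  out <- do.call(rbind, kept)
  # u vs 2u: for each kept array, look for an overlapping candidate with a
  # divisor unit length and identity within 0.02 -- take the smallest
  for (i in seq_len(nrow(out))) {
    divs <- cand[cand$start <= out$end[i] & cand$end >= out$start[i] &
                   out$unit_len[i] %% cand$unit_len == 0 &
                   cand$unit_len < out$unit_len[i] &
                   cand$identity >= out$identity[i] - 0.02, , drop = FALSE]
    if (nrow(divs)) {
      best <- divs[order(divs$unit_len, -divs$score), ][1, ]
      out[i, ] <- best
    }
  }
  out <- out[order(out$start), , drop = FALSE]
  out$score <- NULL
  rownames(out) <- NULL
  out
}

#' Scan for a C-terminal motif
#'
#' Finds the best match of `pattern` (exact residues, `x`/`.` wildcard
#' positions) within the last `window` residues; `found` requires a match
#' fraction at or above `min_score`. X residues in the protein count as
#' mismatches.
#'
#' @param protein Protein string.
#' @param pattern Motif pattern; no default is provided because the
#'   conserved SFTP motif is configuration, not package biology (tests use
#'   the synthetic placeholder [sftp_cterm_motif()]).
#' @param window C-terminal window length (residues).
#' @param min_score Minimum fraction of matching pattern positions.
#' @return A `motif_match`: found, position (1-based), distance from the
#'   C-terminus (residues after the match), score.
#' @export
scan_cterminal_motif <- function(protein, pattern, window = 50L,
                                 min_score = 0.8) {
  .check(nzchar(pattern), "empty motif pattern")
  ch <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  wild <- pat %in% c("X", ".")
  n <- length(ch); m <- length(pat)
  lo <- max(1L, n - window + 1L)
  best <- list(score = -1, pos = NA_integer_)
  if (n >= m) {
    for (i in seq.int(lo, n - m + 1L)) {
      win <- ch[i:(i + m - 1L)]
      sc <- mean(wild | (win == pat & win != "X"))
      if (sc > best$score) best <- list(score = sc, pos = i)
    }
  }
  found <- best$score >= min_score
  structure(list(pattern = pattern, found = found,
                 position = if (found) best$pos else NA_integer_,
                 distance_from_cterm = if (found) n - (best$pos + m - 1L)
                                       else NA_integer_,
                 score = max(best$score, 0)),
            class = "motif_match")
}

#' @export
print.motif_match <- function(x, ...) {
  cat(sprintf("motif_match '%s': %s (score %.2f%s)\n", x$pattern,
              if (x$found) "found" else "absent", x$score,
              if (x$found) sprintf(", %d aa from C-terminus",
                                   x$distance_from_cterm) else ""))
  invisible(x)
}

#' Split a protein into N-terminal, repeat and C-terminal segments
#'
#' @param protein Protein string.
#' @param repeats Repeat annotation from [detect_repeats()].
#' @return List with `n_term`, `repeat_region`, `c_term`, each a
#'   `c(from, to)` 1-based inclusive residue span (`c(NA, NA)` for an
#'   empty segment); attribute `flagged` when no repeats were supplied
#'   (whole protein returned as N-terminal).
#' @export
segment_architecture <- function(protein, repeats) {
  n <- nchar(protein)
  if (is.null(repeats) || nrow(repeats) == 0L) {
    return(structure(list(n_term = c(1L, n),
                          repeat_region = c(NA_integer_, NA_integer_),
                          c_term = c(NA_integer_, NA_integer_)),
                     flagged = TRUE))
  }
  r0 <- min(repeats$start); r1 <- max(repeats$end)
  list(n_term = if (r0 > 1L) c(1L, r0 - 1L) else c(NA_integer_, NA_integer_),
       repeat_region = c(r0, r1),
       c_term = if (r1 < n) c(r1 + 1L, n) else c(NA_integer_, NA_integer_))
}

#' Composition table for a set of proteins
#'
#' @param proteins Named character vector.
#' @return Data frame: one row per protein with length, top-2 residues and
#'   their combined percentage, plus per-residue percentages.
#' @export
composition_table <- function(proteins) {
  rows <- lapply(names(proteins), function(id) {
    cp <- aa_composition(proteins[[id]], id)
    cbind(data.frame(protein = id, length = cp$length,
                     top2 = paste(cp$top2, collapse = "+"),
                     top2_pct = round(100 * cp$top2_fraction, 1)),
          as.data.frame(as.list(round(100 * cp$freq, 2))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
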