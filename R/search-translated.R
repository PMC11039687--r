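# Translated protein-vs-genome search: six-frame translation of the
# scaffolds, exact-word seeding, x-drop ungapped extension along the
# diagonal, and gapped refinement by local dynamic programming
# (Biostrings::pairwiseAlignment). No E-value statistics are computed; raw
# score and identity thresholds are sufficient for intra-cluster
# annotation.
#
# Frames are numbered 0-2 on each strand; minus-strand hits are always
# reported in forward-scaffold coordinates (0-based half-open).

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

#' Default translated-search parameters
#'
#' BLAST-like conventions: BLOSUM62, gap open 11, gap extend 1, exact-match
#' seed words of 4 residues, x-drop 20 for ungapped extension, minimum
#' reported score 40.
#'
#' @param seed_length Exact-match seed word length (residues).
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + gap_extend * L`).
#' @param x_drop Ungapped extension termination threshold.
#' @param min_score Minimum raw score of a reported HSP.
#' @param min_ungapped Minimum ungapped score to enter gapped refinement.
#' @return A named list of parameters.
#' @export
search_params <- function(seed_length = 4L, gap_open = 11, gap_extend = 1,
                          x_drop = 20, min_score = 40, min_ungapped = 35) {
  list(seed_length = as.integer(seed_length), gap_open = gap_open,
       gap_extend = gap_extend, x_drop = x_drop, min_score = min_score,
       min_ungapped = min_ungapped)
}

#' Precompute the six-frame translation index of a scaffold set
#'
#' @param scaffolds Named character vector of DNA scaffolds.
#' @return A `six_frame_index` reusable across queries.
#' @export
six_frame_index <- function(scaffolds) {
  .check(!is.null(names(scaffolds)), "scaffolds must be named")
  idx <- lapply(names(scaffolds), function(id) {
    seq <- scaffolds[[id]]
    L <- nchar(seq)
    frames <- list()
    for (strand in c("+", "-")) {
      for (frame in 0:2) {
        if (L < frame + 3L) next
        prot <- translate_dna(seq, frame, strand)
        chars <- strsplit(prot, "", fixed = TRUE)[[1]]
        frames[[length(frames) + 1L]] <-
          list(strand = strand, frame = frame, prot = prot, chars = chars,
               kmers = .kmers(chars, 4L))
      }
    }
    list(id = id, length = L, frames = frames)
  })
  names(idx) <- names(scaffolds)
  structure(idx, class = "six_frame_index")
}

# kmer vector of a character vector (1-based start positions)
.kmers <- function(chars, k) {
  n <- length(chars)
  if (n < k) return(character(0))
  s <- paste(chars, collapse = "")
  substring(s, 1:(n - k + 1L), k:n)
}

# x-drop ungapped extension over a vector of per-position scores
.best_ext <- function(s, x_drop) {
  if (!length(s)) return(c(len = 0, score = 0))
  cum <- cumsum(s)
  cm <- cummax(cum)
  dead <- which(cum < cm - x_drop)
  end <- if (length(dead)) dead[1] - 1L else length(s)
  if (end == 0L) return(c(len = 0, score = 0))
  i <- which.max(cum[seq_len(end)])
  if (cum[i] <= 0) c(len = 0, score = 0) else c(len = i, score = cum[i])
}

# map a frame-residue span [i1, i2] (1-based, inclusive) to a forward
# 0-based half-open genomic interval
.frame_to_genomic <- function(i1, i2, frame, strand, L) {
  a <- frame + 3L * (i1 - 1L)
  b <- frame + 3L * i2
  if (strand == "+") c(a, b) else c(L - b, L - a)
}

#' Translated search of a protein query against genome scaffolds
#'
#' For each strand and frame, exact-match seed words from the (optionally
#' masked) query are located in the translation, extended ungapped in both
#' directions under an x-drop rule, deduplicated per diagonal, and the
#' survivors refined by gapped local alignment. Overlapping HSPs in the
#' same frame are merged to the best-scoring one; results are sorted by
#' score, descending.
#'
#' Masked (lowercase) query residues never initiate seeds but participate
#' in extension with their uppercase scores.
#'
#' @param query Named character vector of length 1 (protein, possibly
#'   lowercased by [mask_low_complexity()]), or longer (searched in turn).
#' @param genome Named character vector of DNA scaffolds, or a
#'   [six_frame_index()].
#' @param params See [search_params()].
#' @return A data frame of class `hsp_table`: query_id, scaffold_id,
#'   strand, frame, qstart, qend (1-based residues, inclusive), gstart,
#'   gend (0-based half-open forward scaffold coordinates), score, pident,
#'   alen, qaln, taln.
#' @export
search_translated <- function(query, genome, params = search_params()) {
  if (!inherits(genome, "six_frame_index")) genome <- six_frame_index(genome)
  .check(!is.null(names(query)), "query must be named")
  if (length(query) > 1L) {
    out <- do.call(rbind, lapply(names(query), function(q) {
      search_translated(query[q], genome, params)
    }))
    return(structure(out, class = c("hsp_table", "data.frame")))
  }
  qid <- names(query)
  q_raw <- query[[1]]
  q_up <- toupper(q_raw)
  qc <- strsplit(q_up, "", fixed = TRUE)[[1]]
  qlen <- length(qc)
  k <- params$seed_length
  .check(qlen >= k, "query shorter than seed length")
  M <- .blosum62()

  # seedable query word positions: all residues unmasked, no X/stop
  q_mask <- strsplit(q_raw, "", fixed = TRUE)[[1]]
  seedable <- q_mask %in% rownames(M) & q_mask == toupper(q_mask) &
    !(q_mask %in% c("X", "*"))
  ok_word <- if (qlen >= k) {
    vapply(1:(qlen - k + 1L), function(i) all(seedable[i:(i + k - 1L)]), TRUE)
  } else logical(0)
  qk <- .kmers(qc, k)
  qmap <- split(which(ok_word), qk[ok_word])

  rows <- list()
  for (scf in genome) {
    L <- scf$length
    for (fr in scf$frames) {
      tc <- fr$chars
      tlen <- length(tc)
      if (tlen < k) next
      tk <- if (k == 4L && !is.null(fr$kmers)) fr$kmers else .kmers(tc, k)
      hit_t <- which(tk %in% names(qmap))
      if (!length(hit_t)) next
      # expand to (qpos, tpos) seed pairs
      qpos_list <- qmap[tk[hit_t]]
      reps <- lengths(qpos_list)
      seeds <- data.frame(q = unlist(qpos_list, use.names = FALSE),
                          t = rep(hit_t, reps))
      seeds$diag <- seeds$t - seeds$q
      seeds <- seeds[order(seeds$diag, seeds$q), , drop = FALSE]
      covered_diag <- -Inf; covered_q <- -Inf
      ug <- list()
      for (i in seq_len(nrow(seeds))) {
        qs <- seeds$q[i]; ts <- seeds$t[i]; dg <- seeds$diag[i]
        if (dg == covered_diag && qs <= covered_q) next
        seed_score <- sum(M[cbind(qc[qs:(qs + k - 1L)], tc[ts:(ts + k - 1L)])])
        # right extension
        nr <- min(qlen - (qs + k - 1L), tlen - (ts + k - 1L))
        sr <- if (nr > 0) M[cbind(qc[(qs + k):(qs + k - 1L + nr)],
                                  tc[(ts + k):(ts + k - 1L + nr)])] else numeric(0)
        er <- .best_ext(sr, params$x_drop)
        # left extension
        nl <- min(qs - 1L, ts - 1L)
        sl <- if (nl > 0) M[cbind(qc[(qs - 1L):(qs - nl)],
                                  tc[(ts - 1L):(ts - nl)])] else numeric(0)
        el <- .best_ext(sl, params$x_drop)
        q1 <- qs - el["len"]; q2 <- qs + k - 1L + er["len"]
        score <- seed_score + el["score"] + er["score"]
        covered_diag <- dg; covered_q <- q2
        if (score < params$min_ungapped) next
        ug[[length(ug) + 1L]] <- c(q1 = q1, q2 = q2, t1 = ts - el["len"],
                                   t2 = ts + k - 1L + er["len"], score = score)
      }
      if (!length(ug)) next
      ug <- as.data.frame(do.call(rbind, ug))
      names(ug) <- c("q1", "q2", "t1", "t2", "score")
      # dedupe overlapping ungapped HSPs (same frame): keep best per group
      ug <- ug[order(-ug$score), , drop = FALSE]
      keep <- rep(TRUE, nrow(ug))
      for (i in seq_len(nrow(ug))) {
        if (!keep[i]) next
        if (i < nrow(ug)) {
          j <- (i + 1L):nrow(ug)
          ov <- pmin(ug$t2[j], ug$t2[i]) - pmax(ug$t1[j], ug$t1[i]) + 1L
          span <- pmin(ug$t2[j] - ug$t1[j], ug$t2[i] - ug$t1[i]) + 1L
          keep[j][ov > 0.3 * span] <- FALSE
        }
      }
      ug <- ug[keep, , drop = FALSE]
      for (i in seq_len(nrow(ug))) {
        # a near-full-coverage ungapped extension is already the local
        # alignment; skip the DP refinement in that case
        if (ug$q2[i] - ug$q1[i] + 1L >= 0.9 * qlen) {
          if (ug$score[i] < params$min_score) next
          qa_c <- qc[ug$q1[i]:ug$q2[i]]
          ta_c <- tc[ug$t1[i]:ug$t2[i]]
          gsp <- .frame_to_genomic(ug$t1[i], ug$t2[i], fr$frame, fr$strand, L)
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = qid, scaffold_id = scf$id, strand = fr$strand,
            frame = fr$frame, qstart = ug$q1[i], qend = ug$q2[i],
            gstart = gsp[1], gend = gsp[2], score = ug$score[i],
            pident = round(100 * mean(qa_c == ta_c), 2),
            alen = length(qa_c), qaln = paste(qa_c, collapse = ""),
            taln = paste(ta_c, collapse = ""), stringsAsFactors = FALSE)
          next
        }
        # gapped refinement over a modestly padded window; introns break
        # the reading frame, so wider windows would only let the DP bridge
        # into neighbouring exons (chaining joins exons instead)
        pad <- 40L
        w1 <- max(1L, ug$t1[i] - pad)
        w2 <- min(tlen, ug$t2[i] + pad)
        subj <- substr(fr$prot, w1, w2)
        aln <- Biostrings::pairwiseAlignment(
          q_up, subj, type = "local", substitutionMatrix = M,
          gapOpening = params$gap_open, gapExtension = params$gap_extend)
        sc <- as.numeric(Biostrings::score(aln))
        if (sc < params$min_score) next
        qa <- as.character(Biostrings::alignedPattern(aln))
        ta <- as.character(Biostrings::alignedSubject(aln))
        p <- Biostrings::pattern(aln)
        s <- Biostrings::subject(aln)
        i1 <- w1 + Biostrings::start(s) - 1L
        i2 <- w1 + Biostrings::end(s) - 1L
        gsp <- .frame_to_genomic(i1, i2, fr$frame, fr$strand, L)
        qa_c <- strsplit(qa, "", fixed = TRUE)[[1]]
        ta_c <- strsplit(ta, "", fixed = TRUE)[[1]]
        ident <- sum(qa_c == ta_c & qa_c != "-") / length(qa_c)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = qid, scaffold_id = scf$id, strand = fr$strand,
          frame = fr$frame, qstart = Biostrings::start(p),
          qend = Biostrings::end(p), gstart = gsp[1], gend = gsp[2],
          score = sc, pident = round(100 * ident, 2),
          alen = length(qa_c), qaln = qa, taln = ta,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(query_id = character(0), scaffold_id = character(0),
                      strand = character(0), frame = integer(0),
                      qstart = integer(0), qend = integer(0),
                      gstart = integer(0), gend = integer(0),
                      score = numeric(0), pident = numeric(0),
                      alen = integer(0), qaln = character(0),
                      taln = character(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("hsp_table", "data.frame")))
  }
  out <- do.call(rbind, rows)
  # merge overlapping refined HSPs in the same scaffold/strand/frame
  out <- out[order(-out$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(out)) > i &
                 out$scaffold_id == out$scaffold_id[i] &
                 out$strand == out$strand[i] & out$frame == out$frame[i])
    if (length(j)) {
      ov <- pmin(out$gend[j], out$gend[i]) - pmax(out$gstart[j], out$gstart[i])
      span <- pmin(out$gend[j] - out$gstart[j], out$gend[i] - out$gstart[i])
      keep[j][ov > 0.3 * span] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hsp_table", "data.frame"))
}

#' Recompute an HSP score from its reported alignment
#'
#' Sums substitution-matrix values over aligned columns and subtracts
#' affine gap costs (`gap_open + gap_extend * L` per gap run), so every
#' reported HSP score can be verified independently of the search path.
#'
#' @param qaln,taln Gapped aligned strings of equal length.
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Numeric score.
#' @export
hsp_score <- function(qaln, taln, gap_open = 11, gap_extend = 1) {
  M <- .blosum62()
  qc <- strsplit(qaln, "", fixed = TRUE)[[1]]
  tc <- strsplit(taln, "", fixed = TRUE)[[1]]
  .check(length(qc) == length(tc), "aligned strings differ in length")
  gap <- qc == "-" | tc == "-"
  score <- sum(M[cbind(qc[!gap], tc[!gap])])
  r <- rle(gap)
  runs <- r$lengths[r$values]
  score - sum(gap_open + gap_extend * runs)
}

#' Write an HSP table as BLAST outfmt-6-like TSV
#'
#' Columns: query, scaffold, percent identity, alignment length, qstart,
#' qend (1-based residues), sstart, send (1-based closed genomic), frame,
#' strand, score. Minus-strand hits keep forward-scaffold coordinates.
#'
#' @param hsps An `hsp_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hsps, path) {
  df <- data.frame(query = hsps$query_id, scaffold = hsps$scaffold_id,
                   pident = hsps$pident, length = hsps$alen,
                   qstart = hsps$qstart, qend = hsps$qend,
                   sstart = hsps$gstart + 1L, send = hsps$gend,
                   frame = hsps$frame, strand = hsps$strand,
                   score = hsps$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
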