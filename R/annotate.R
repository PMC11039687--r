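# Locus assembly and gene-model reconstruction: HSPs from one query are
# chained into loci, and an exon/CDS model is rebuilt over each locus
# guided by an intact ortholog template. Architecture is classified from
# the coding-exon count plus an S100-domain consensus score on the first
# coding segment (one coding exon = SEDC; two with an N-terminal S100
# domain = SFTP).

#' Chain HSPs of one query into candidate loci
#'
#' HSPs are grouped by scaffold and strand; within a group a chain is a
#' maximal set collinear in both query and genome (in transcription
#' orientation) whose genomic gaps do not exceed `max_intron`. Chains are
#' scored by summed HSP score and extracted best-first; ties break to the
#' leftmost genomic start.
#'
#' @param hsps An `hsp_table` from a single query.
#' @param max_intron Largest tolerated genomic gap within a locus (bp).
#' @return List of loci; each locus is a list with `scaffold_id`, `strand`,
#'   `start`, `end` (0-based half-open), `score` and `hsps` (the member
#'   rows). Sorted by score, descending.
#' @export
chain_hsps <- function(hsps, max_intron = 10000L) {
  if (nrow(hsps) == 0L) return(list())
  .check(length(unique(hsps$query_id)) == 1L,
         "chain_hsps expects HSPs from a single query")
  loci <- list()
  for (key in unique(paste(hsps$scaffold_id, hsps$strand))) {
    h <- hsps[paste(hsps$scaffold_id, hsps$strand) == key, , drop = FALSE]
    # transcription order: genomic start ascending on +, descending on -
    ord <- if (h$strand[1] == "+") order(h$gstart, -h$score)
           else order(-h$gend, -h$score)
    h <- h[ord, , drop = FALSE]
    n <- nrow(h)
    used <- rep(FALSE, n)
    repeat {
      avail <- which(!used)
      if (!length(avail)) break
      # DP over available HSPs in transcription order
      dp <- h$score; prev <- rep(NA_integer_, n)
      for (ii in seq_along(avail)) {
        i <- avail[ii]
        for (jj in seq_len(ii - 1L)) {
          j <- avail[jj]
          gap <- if (h$strand[1] == "+") h$gstart[i] - h$gend[j]
                 else h$gstart[j] - h$gend[i]
          # a chain member must contribute meaningful new query coverage
          # (>= 15 residues), otherwise short spurious HSPs far away can
          # inflate the locus span
          q_ok <- h$qstart[i] > h$qstart[j] & h$qend[i] >= h$qend[j] + 15L &
            h$qstart[i] >= h$qend[j] - 30L
          if (q_ok && gap > -9L && gap <= max_intron &&
              dp[j] + h$score[i] > dp[i]) {
            dp[i] <- dp[j] + h$score[i]
            prev[i] <- j
          }
        }
      }
      best <- avail[which.max(dp[avail])]
      chain <- best
      while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
      used[chain] <- TRUE
      mem <- h[chain, , drop = FALSE]
      loci[[length(loci) + 1L]] <- list(
        scaffold_id = mem$scaffold_id[1], strand = mem$strand[1],
        start = min(mem$gstart), end = max(mem$gend),
        score = sum(mem$score), query_id = mem$query_id[1], hsps = mem)
    }
  }
  ord <- order(-vapply(loci, function(l) as.numeric(l$score), 0),
               vapply(loci, function(l) as.numeric(l$start), 0))
  loci[ord]
}

#' Build an exon template from an intact gene unit
#'
#' A template records the intact ortholog's sense-strand gene sequence,
#' its exon/CDS layout and the encoded protein; gene models and lesion
#' reports are reconstructed against it.
#'
#' @param unit A gene unit as stored in an `edc_cluster`'s `templates`
#'   list, or a list with fields `name`, `dna`, `exons` (sense-local
#'   0-based half-open, columns start/end/coding/phase), and optionally
#'   `family`/`architecture`.
#' @return The unit, classed `exon_template`, with derived fields
#'   `cds`, `protein` and `segments` (per coding exon protein segments).
#' @export
exon_template <- function(unit) {
  .check(all(c("name", "dna", "exons") %in% names(unit)),
         "template needs name, dna, exons")
  ex <- unit$exons[order(unit$exons$start), , drop = FALSE]
  cds <- paste(vapply(which(ex$coding), function(i) {
    substr(unit$dna, ex$start[i] + 1L, ex$end[i])
  }, ""), collapse = "")
  protein <- sub("\\*$", "", translate_dna(cds, 0L, "+"))
  # per-coding-exon protein segments (residue intervals, 1-based)
  segs <- list()
  off <- 0L
  for (i in which(ex$coding)) {
    w <- ex$end[i] - ex$start[i]
    segs[[length(segs) + 1L]] <- c(from = off %/% 3L + 1L,
                                   to = (off + w) %/% 3L)
    off <- off + w
  }
  out <- unit
  out$exons <- ex
  out$cds <- cds
  out$protein <- protein
  out$segments <- segs
  structure(out, class = "exon_template")
}

#' Reconstruct a gene model over a locus using an ortholog template
#'
#' The intact template gene is aligned (DNA level, template global) into
#' the locus region; template exon boundaries are carried through the
#' alignment, then refined to the nearest GT..AG intron boundaries within
#' 30 bp that preserve the template reading frame. The start codon is
#' checked at the mapped template start (searched among in-frame ATGs
#' within 30 bp if absent). Failures raise flags rather than dropping the
#' model.
#'
#' @param locus A locus from [chain_hsps()].
#' @param template An [exon_template()] (a raw unit is accepted).
#' @param scaffolds Named character vector holding the locus scaffold.
#' @param margin Extra region sequence taken on both sides of the locus
#'   span (bp); must cover the template's non-coding leader.
#' @return A list of class `gene_model`: name, scaffold_id, strand, exons
#'   (scaffold 0-based half-open with coding/phase), cds_dna, protein,
#'   architecture, source, region (interval used) and flags.
#' @export
build_gene_model <- function(locus, template, scaffolds, margin = 800L) {
  if (!inherits(template, "exon_template")) template <- exon_template(template)
  seq <- scaffolds[[locus$scaffold_id]]
  .check(!is.null(seq), "locus scaffold not found")
  L <- nchar(seq)
  r0 <- max(0L, locus$start - margin)
  r1 <- min(L, locus$end + margin)
  region <- substr(seq, r0 + 1L, r1)
  sense_region <- if (locus$strand == "-") reverse_complement(region) else region
  map <- .align_map(template$dna, sense_region)
  t2t <- .template_to_target(map, nchar(template$dna))
  flags <- character(0)

  ex <- template$exons
  n <- nrow(ex)
  # carry boundaries through the alignment (sense-region coordinates)
  m_start <- m_end <- integer(n)
  for (i in seq_len(n)) {
    s_cand <- t2t[(ex$start[i] + 1L):ex$end[i]]
    s_ok <- which(!is.na(s_cand))
    if (!length(s_ok)) {
      m_start[i] <- NA_integer_; m_end[i] <- NA_integer_
      flags <- c(flags, sprintf("exon%d_unmapped", i))
      next
    }
    m_start[i] <- s_cand[s_ok[1]] - (s_ok[1] - 1L)
    m_end[i] <- s_cand[s_ok[length(s_ok)]] + (ex$end[i] - ex$start[i] - s_ok[length(s_ok)]) + 1L
  }

  # refine intron boundaries to GT..AG preserving frame
  rc <- function(p) substr(sense_region, p + 1L, p + 2L)
  for (i in seq_len(n - 1L)) {
    if (is.na(m_end[i]) || is.na(m_start[i + 1L])) next
    don <- m_end[i]; acc <- m_start[i + 1L] - 2L
    if (rc(don) == "GT" && rc(acc) == "AG") next
    found <- FALSE
    for (d in as.vector(rbind(1:30, -(1:30)))) {  # 1, -1, 2, -2, ...
      don2 <- don + d
      # equal shift of both ends keeps intron length and frame
      if (don2 >= 0 && acc + d >= 0 && rc(don2) == "GT" && rc(acc + d) == "AG") {
        m_end[i] <- don2; m_start[i + 1L] <- acc + d + 2L
        found <- TRUE; break
      }
    }
    if (!found) flags <- c(flags, sprintf("splice_unresolved_intron%d", i))
  }

  # start codon at the mapped template CDS start
  first_cd <- which(ex$coding)[1]
  if (!is.na(m_start[first_cd])) {
    cs <- m_start[first_cd]
    if (substr(sense_region, cs + 1L, cs + 3L) != "ATG") {
      hit <- NA_integer_
      for (d in seq(3L, 30L, by = 3L)) {
        for (cand in c(cs + d, cs - d)) {
          if (cand >= 0 && substr(sense_region, cand + 1L, cand + 3L) == "ATG") {
            hit <- cand; break
          }
        }
        if (!is.na(hit)) break
      }
      if (is.na(hit)) flags <- c(flags, "start_codon_missing")
    }
  }

  # convert sense-region coordinates to scaffold coordinates
  rlen <- nchar(sense_region)
  to_scaffold <- function(a, b) {
    if (locus$strand == "+") c(r0 + a, r0 + b) else c(r0 + rlen - b, r0 + rlen - a)
  }
  rows <- lapply(seq_len(n), function(i) {
    if (is.na(m_start[i])) return(NULL)
    sp <- to_scaffold(m_start[i], m_end[i])
    data.frame(start = sp[1], end = sp[2], coding = ex$coding[i],
               phase = ex$phase[i], sense_index = i)
  })
  exons <- do.call(rbind, rows)
  if (is.null(exons) || nrow(exons) == 0L) {
    return(structure(list(
      name = template$name, query_id = locus$query_id,
      scaffold_id = locus$scaffold_id, strand = locus$strand,
      exons = data.frame(start = integer(0), end = integer(0),
                         coding = logical(0), phase = integer(0)),
      cds_dna = "", protein = "", architecture = "other",
      source = "template_guided", region = c(start = r0, end = r1),
      flags = c(flags, "no_exon_mapped")), class = "gene_model"))
  }
  cds_dna <- paste(vapply(which(!is.na(m_start) & ex$coding), function(i) {
    substr(sense_region, m_start[i] + 1L, m_end[i])
  }, ""), collapse = "")
  protein <- if (nchar(cds_dna) >= 3L) {
    sub("\\*.*$", "", translate_dna(cds_dna, 0L, "+"))
  } else ""
  model <- structure(list(
    name = template$name, query_id = locus$query_id,
    scaffold_id = locus$scaffold_id, strand = locus$strand,
    exons = exons[order(exons$start), , drop = FALSE],
    cds_dna = cds_dna, protein = protein,
    source = "template_guided", region = c(start = r0, end = r1),
    flags = flags), class = "gene_model")
  model$architecture <- if (length(flags)) "other" else classify_architecture(model)
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s [%s %s:%d-%d] %s, %d exons, protein %d aa%s\n",
              x$name, x$architecture, x$scaffold_id,
              min(x$exons$start) + 1L, max(x$exons$end), x$strand,
              nrow(x$exons), nchar(x$protein),
              if (length(x$flags)) paste0(" flags:", paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# S100 consensus profile and architecture

#' Position-weight consensus profile for the S100-like domain
#'
#' Builds a log-odds profile from one or more aligned equal-length domain
#' sequences (default: the packaged synthetic consensus). Scoring a window
#' sums per-position log-odds; the profile's score against its own
#' consensus defines the reference self-score.
#'
#' @param proteins Character vector of equal-length domain sequences.
#' @param pseudocount Per-residue pseudocount weight.
#' @return List of class `s100_profile` with `pwm` (20 x width log-odds),
#'   `width`, `self_score`.
#' @export
s100_profile <- function(proteins = s100_consensus(), pseudocount = 0.05) {
  w <- unique(nchar(proteins))
  .check(length(w) == 1L, "profile sequences must be aligned (equal length)")
  aa <- setdiff(names(.aa_codons()), "*")
  mat <- do.call(rbind, strsplit(proteins, "", fixed = TRUE))
  bg <- 1 / length(aa)
  pwm <- vapply(seq_len(w), function(j) {
    f <- tabulate(factor(mat[, j], levels = aa), nbins = length(aa))
    p <- (f + pseudocount) / (sum(f) + pseudocount * length(aa))
    log2(p / bg)
  }, numeric(length(aa)))
  rownames(pwm) <- aa
  self <- sum(vapply(seq_len(w), function(j) max(pwm[, j]), 0))
  structure(list(pwm = pwm, width = w, self_score = self),
            class = "s100_profile")
}

# best sliding-window profile score over a protein (X scores 0)
.profile_score <- function(protein, profile) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  w <- profile$width
  n <- length(ch)
  if (n < w) return(-Inf)
  best <- -Inf
  for (i in seq_len(n - w + 1L)) {
    win <- ch[i:(i + w - 1L)]
    idx <- cbind(match(win, rownames(profile$pwm)), seq_len(w))
    v <- profile$pwm[idx]
    v[is.na(v)] <- 0
    best <- max(best, sum(v))
  }
  best
}

#' Classify gene architecture from a gene model
#'
#' One coding exon is a SEDC (single-coding-exon EDC gene). Two coding
#' exons whose first coding segment carries the S100-domain consensus
#' (profile score at least `threshold` times the profile self-score) is an
#' SFTP (S100 fused-type protein). Anything else is "other".
#'
#' @param model A `gene_model` (or any list with `exons`, `cds_dna`).
#' @param profile An [s100_profile()].
#' @param threshold Fraction of the profile self-score required.
#' @return One of "SEDC", "SFTP", "other".
#' @export
classify_architecture <- function(model, profile = s100_profile(),
                                  threshold = 0.6) {
  ex <- model$exons
  .check(!is.null(ex) && nrow(ex) >= 1L, "model has no exons")
  n_coding <- sum(ex$coding)
  if (n_coding == 1L) return("SEDC")
  if (n_coding == 2L) {
    ci <- which(ex$coding)
    first <- ci[if (!is.null(model$strand) && model$strand == "-") 2L else 1L]
    seg_dna_len <- ex$end[first] - ex$start[first]
    seg_prot <- substr(model$protein, 1L, seg_dna_len %/% 3L)
    if (.profile_score(seg_prot, profile) >= threshold * profile$self_score) {
      return("SFTP")
    }
    return("other")
  }
  "other"
}
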