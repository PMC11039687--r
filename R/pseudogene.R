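# Detection of inactivating lesions in a locus relative to an intact
# ortholog template, and gene-status classification. The locus region is
# aligned to the template at the DNA level (template global); lesions are
# read off the alignment:
#   - a target triplet on the template codon grid equal to TAA/TAG/TGA
#     before the template's final codon -> premature_stop (codon index on
#     the template CDS). Out-of-frame stops downstream of a frameshift are
#     not on the grid and are deliberately not called.
#   - an indel run inside a coding exon whose length mod 3 != 0 ->
#     frameshift, at the left-normalized indel position.
#   - a mutated GT donor / AG acceptor at a template intron boundary ->
#     splice_loss at the mutated base.
#   - a template coding exon with less than 20% of its bases aligned ->
#     missing_exon at the deletion junction.
#   - no ATG at the template start codon -> start_loss.

#' Scan a locus for inactivating lesions against an intact template
#'
#' @param scaffolds Named character vector holding the locus scaffold.
#' @param region List or one-row data frame with `scaffold_id`, `start`,
#'   `end`, `strand` (0-based half-open scaffold interval containing the
#'   gene, e.g. a [chain_hsps()] locus span plus margin, or a truth gene
#'   row).
#' @param template An [exon_template()] (raw unit accepted).
#' @param margin Extra sequence taken on both sides of the region.
#' @return A `disruption_report`: gene, lesions data frame (kind,
#'   genomic_pos, codon_index, detail), longest_orf_fraction, status,
#'   flags.
#' @export
detect_disruptions <- function(scaffolds, region, template, margin = 0L) {
  if (!inherits(template, "exon_template")) template <- exon_template(template)
  scf_id <- if (!is.null(region$scaffold_id)) region$scaffold_id else region$scaffold
  seq <- scaffolds[[scf_id]]
  .check(!is.null(seq), "region scaffold not found")
  L <- nchar(seq)
  r0 <- max(0L, region$start - margin)
  r1 <- min(L, region$end + margin)
  strand <- region$strand
  region_fwd <- substr(seq, r0 + 1L, r1)
  sense_region <- if (strand == "-") reverse_complement(region_fwd) else region_fwd
  rlen <- nchar(sense_region)
  # sense-region [a, b) -> forward scaffold 0-based start of the span
  to_scaffold <- function(a, len) {
    if (strand == "+") r0 + a else r0 + rlen - a - len
  }

  tlen <- nchar(template$dna)
  n_codons <- nchar(template$cds) %/% 3L
  flags <- character(0)
  lesions <- list()
  add <- function(kind, gpos, ci, detail) {
    lesions[[length(lesions) + 1L]] <<- data.frame(
      gene = template$name, kind = kind, genomic_pos = as.integer(gpos),
      codon_index = ci, detail = detail, stringsAsFactors = FALSE)
  }

  # degenerate locus: nothing alignable at meaningful length
  if (rlen < 0.05 * tlen) {
    for (i in which(template$exons$coding)) {
      add("missing_exon", r0, template$exons$start[i] %/% 3L + 1L,
          sprintf("exon%d_unalignable", i))
    }
    rep <- structure(list(gene = template$name,
                          lesions = do.call(rbind, lesions),
                          longest_orf_fraction = 0, status = "pseudogene",
                          flags = "locus_too_short"),
                     class = "disruption_report")
    return(rep)
  }

  map <- .align_map(template$dna, sense_region)
  t2t <- .template_to_target(map, tlen)
  runs <- .indel_runs(map)
  sense_chars <- strsplit(sense_region, "", fixed = TRUE)[[1]]
  tpl_chars <- strsplit(template$dna, "", fixed = TRUE)[[1]]

  ex <- template$exons
  coding_idx <- which(ex$coding)
  # template position -> CDS offset
  cds_off <- rep(NA_integer_, tlen)
  off <- 0L
  for (i in coding_idx) {
    w <- ex$end[i] - ex$start[i]
    cds_off[(ex$start[i] + 1L):ex$end[i]] <- off + seq_len(w) - 1L
    off <- off + w
  }

  missing <- logical(length(coding_idx))
  for (k in seq_along(coding_idx)) {
    i <- coding_idx[k]
    span <- (ex$start[i] + 1L):ex$end[i]
    mapped <- mean(!is.na(t2t[span]))
    # identity over the exon (unmapped positions count as mismatch): a
    # deleted exon sometimes cross-aligns to a paralogous neighbour, which
    # sits far below any real within- or between-species divergence
    ident <- mean(!is.na(t2t[span]) &
                    sense_chars[t2t[span] + 1L] == tpl_chars[span])
    if (mapped < 0.2 || ident < 0.7) {
      missing[k] <- TRUE
      # junction: the target position following the last aligned template
      # base upstream of the exon (falls back to the first aligned one
      # downstream, then the region edge)
      before <- t2t[seq_len(tlen) <= ex$start[i]]
      before <- before[!is.na(before)]
      junct_sense <- if (length(before)) before[length(before)] + 1L else {
        after <- t2t[seq_len(tlen) > ex$end[i]]
        c(after[!is.na(after)], rlen)[1]
      }
      # left-normalize the deletion block like a long indel
      kk <- ex$end[i] - ex$start[i]
      a <- .normalize_indel_left(template$dna, ex$start[i], kk)
      junct_sense <- junct_sense - (ex$start[i] - a)
      add("missing_exon", to_scaffold(junct_sense, 0L),
          cds_off[ex$start[i] + 1L] %/% 3L + 1L,
          sprintf("exon%d_missing", i))
    }
  }

  # frameshifts: indel runs with length mod 3 != 0 inside surviving exons
  if (nrow(runs)) {
    for (r in seq_len(nrow(runs))) {
      run <- runs[r, ]
      in_exon <- vapply(seq_along(coding_idx), function(k) {
        i <- coding_idx[k]
        !missing[k] && run$tpl >= ex$start[i] + 1L && run$tpl < ex$end[i]
      }, TRUE)
      if (!any(in_exon)) next
      if (run$len %% 3L == 0L) next
      norm <- .normalize_run(run, template$dna, sense_region)
      len_in_target <- if (run$type == "ins") run$len else 0L
      gpos <- to_scaffold(norm$trg, len_in_target)
      ci <- cds_off[norm$tpl + 1L]
      ci <- if (is.na(ci)) NA_integer_ else ci %/% 3L + 1L
      add("frameshift", gpos, ci,
          sprintf("%s%d", if (run$type == "ins") "ins" else "del", run$len))
    }
  }

  # premature stops on the template codon grid
  for (k in seq_along(coding_idx)) {
    i <- coding_idx[k]
    if (missing[k]) next
    starts <- seq.int(ex$start[i], ex$end[i] - 3L, by = 3L)
    # align exon-local codon grid to CDS frame
    starts <- starts[(cds_off[starts + 1L] %% 3L) == 0L]
    for (s in starts) {
      tp <- t2t[(s + 1L):(s + 3L)]
      if (any(is.na(tp)) || tp[3] - tp[1] != 2L) next  # gapped codon
      codon <- paste(sense_chars[tp + 1L], collapse = "")
      ci <- cds_off[s + 1L] %/% 3L + 1L
      if (codon %in% .STOPS && ci < n_codons) {
        add("premature_stop", to_scaffold(tp[1], 3L), ci, codon)
      }
    }
  }

  # splice sites at template intron boundaries
  exonic <- ex[order(ex$start), , drop = FALSE]
  for (i in seq_len(nrow(exonic) - 1L)) {
    don <- exonic$end[i]; acc <- exonic$start[i + 1L] - 2L
    if (acc <= don) next
    for (side in c("donor", "acceptor")) {
      pos2 <- if (side == "donor") don else acc
      want <- if (side == "donor") c("G", "T") else c("A", "G")
      tp <- t2t[(pos2 + 1L):(pos2 + 2L)]
      if (any(is.na(tp))) next
      got <- sense_chars[tp + 1L]
      bad <- which(got != want)
      if (length(bad)) {
        b <- bad[1]
        add("splice_loss", to_scaffold(tp[b], 1L), NA_integer_,
            sprintf("%s %s>%s", side, paste(want, collapse = ""),
                    paste(got, collapse = "")))
      }
    }
  }

  # start codon
  cs <- ex$start[coding_idx[1]]
  if (!missing[1]) {
    tp <- t2t[(cs + 1L):(cs + 3L)]
    if (!any(is.na(tp)) && tp[3] - tp[1] == 2L) {
      codon <- paste(sense_chars[tp + 1L], collapse = "")
      if (codon != "ATG") add("start_loss", to_scaffold(tp[1], 3L), 1L, codon)
    }
  }

  lesions <- if (length(lesions)) do.call(rbind, lesions) else {
    data.frame(gene = character(0), kind = character(0),
               genomic_pos = integer(0), codon_index = integer(0),
               detail = character(0), stringsAsFactors = FALSE)
  }
  lesions <- lesions[order(lesions$genomic_pos), , drop = FALSE]
  rownames(lesions) <- NULL

  stops <- lesions$codon_index[lesions$kind == "premature_stop"]
  orf_frac <- if (length(stops)) (min(stops) - 1L) / n_codons else 1
  status <- classify_status(lesions, n_codons)
  structure(list(gene = template$name, lesions = lesions,
                 longest_orf_fraction = orf_frac, status = status,
                 flags = flags), class = "disruption_report")
}

#' @export
print.disruption_report <- function(x, ...) {
  cat(sprintf("disruption_report %s: status %s, %d lesion(s), ORF fraction %.2f\n",
              x$gene, x$status, nrow(x$lesions), x$longest_orf_fraction))
  if (nrow(x$lesions)) print(x$lesions)
  invisible(x)
}

#' Classify gene status from a lesion table
#'
#' No lesions is intact. Premature stop(s) only, with the first stop at or
#' beyond 20% of the template CDS and no frameshift, splice or exon lesion
#' upstream of it, is truncated (the gene still encodes a shortened
#' protein with an intact start). Anything else with lesions is a
#' pseudogene. Thresholds follow the package defaults used by the
#' generator's truth labels.
#'
#' @param lesions Lesion data frame (columns kind, codon_index) or a
#'   `disruption_report`.
#' @param template_codons Template CDS length in codons (incl. stop).
#' @return "intact", "truncated" or "pseudogene".
#' @export
classify_status <- function(lesions, template_codons) {
  if (inherits(lesions, "disruption_report")) lesions <- lesions$lesions
  les <- lesions
  # the generator distinguishes frameshift_ins/del; the scanner reports
  # "frameshift" -- treat them alike
  les$kind[les$kind %in% c("frameshift_ins", "frameshift_del")] <- "frameshift"
  les$kind[les$kind == "exon_deletion"] <- "missing_exon"
  .status_from_lesions(les, template_codons)
}

#' Count codons until the next in-frame stop
#'
#' Counts complete codons strictly after `position` (0-based) until, and
#' exclusive of, the first stop codon in the frame defined by `position`.
#'
#' @param scaffolds Named character vector, or a single DNA string.
#' @param scaffold_id Scaffold name (ignored for a bare string).
#' @param position 0-based position; counting starts at `position`.
#' @param strand "+" or "-" (minus counts on the reverse complement,
#'   `position` still a forward coordinate of the codon start base).
#' @return List with `codons`, `stop_pos` (0-based forward coordinate of
#'   the stop codon start, NA if none) and `hit_end` flag.
#' @export
measure_orf_runway <- function(scaffolds, position, strand = "+",
                               scaffold_id = NULL) {
  seq <- if (length(scaffolds) == 1L && is.null(names(scaffolds))) scaffolds
         else scaffolds[[scaffold_id %||% names(scaffolds)[1]]]
  L <- nchar(seq)
  .check(position >= 0 && position < L, "position outside scaffold")
  # walk codon by codon, stopping at the first stop; avoids translating
  # the whole suffix
  j <- 0L
  repeat {
    if (strand == "+") {
      a <- position + 3L * j
      if (a + 3L > L) return(list(codons = j, stop_pos = NA_integer_,
                                  hit_end = TRUE))
      codon <- substr(seq, a + 1L, a + 3L)
    } else {
      a <- position - 3L * j - 1L  # 1-based forward start of the j-th codon
      if (a < 1L) return(list(codons = j, stop_pos = NA_integer_,
                              hit_end = TRUE))
      codon <- reverse_complement(substr(seq, a, a + 2L))
    }
    if (codon %in% .STOPS) {
      stop_fwd <- if (strand == "+") a else a - 1L
      return(list(codons = j, stop_pos = as.integer(stop_fwd),
                  hit_end = FALSE))
    }
    j <- j + 1L
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fractional shortening of a protein relative to a reference
#'
#' @param target_len,reference_len Protein lengths in residues.
#' @return `1 - target/reference`, clipped to [0, 1]; a target longer than
#'   the reference yields 0 with attribute `flag = "target_longer"`.
#' @export
shortening_fraction <- function(target_len, reference_len) {
  .check(reference_len > 0, "reference length must be positive")
  v <- 1 - target_len / reference_len
  if (v < 0) return(structure(0, flag = "target_longer"))
  min(v, 1)
}

#' Write a lesion report table as TSV
#'
#' One row per lesion: gene, kind, scaffold, 1-based coordinate, codon
#' index, detail, status.
#'
#' @param reports List of `disruption_report`s.
#' @param path Output path.
#' @param scaffold_id Scaffold name recorded in the table.
#' @return `path`, invisibly.
#' @export
write_lesion_tsv <- function(reports, path, scaffold_id = "") {
  rows <- lapply(reports, function(r) {
    if (nrow(r$lesions) == 0L) {
      return(data.frame(gene = r$gene, kind = "none", scaffold = scaffold_id,
                        pos_1based = NA_integer_, codon_index = NA_integer_,
                        detail = "", status = r$status))
    }
    data.frame(gene = r$gene, kind = r$lesions$kind, scaffold = scaffold_id,
               pos_1based = r$lesions$genomic_pos + 1L,
               codon_index = r$lesions$codon_index,
               detail = r$lesions$detail, status = r$status)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
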