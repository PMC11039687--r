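# GFF3 emission and parsing for gene models. Annotations travel through the
# pipeline as an `edc_annotation`: a genes table plus an exons table, both
# in internal 0-based half-open coordinates; GFF3 is written 1-based closed
# with phase on CDS features.

#' Construct an annotation object
#'
#' @param genes Data frame with columns gene, family, architecture,
#'   scaffold, start, end, strand, status (0-based half-open coordinates).
#' @param exons Data frame with columns gene, exon_index, start, end,
#'   coding (logical), phase (integer, NA for non-coding exons).
#' @return An object of class `edc_annotation`.
#' @export
edc_annotation <- function(genes, exons) {
  need_g <- c("gene", "family", "architecture", "scaffold", "start", "end",
              "strand", "status")
  need_e <- c("gene", "exon_index", "start", "end", "coding", "phase")
  .check(all(need_g %in% names(genes)), "genes table is missing columns")
  .check(all(need_e %in% names(exons)), "exons table is missing columns")
  structure(list(genes = genes, exons = exons), class = "edc_annotation")
}

#' @export
print.edc_annotation <- function(x, ...) {
  cat(sprintf("edc_annotation: %d genes (%s)\n", nrow(x$genes),
              paste(sprintf("%s=%d", names(table(x$genes$family)),
                            as.integer(table(x$genes$family))), collapse = ", ")))
  st <- table(x$genes$status)
  cat(sprintf("status: %s\n",
              paste(sprintf("%s=%d", names(st), as.integer(st)), collapse = ", ")))
  invisible(x)
}

#' Write an annotation as GFF3
#'
#' Emits gene, mRNA, exon and CDS features. Internal 0-based half-open
#' coordinates are converted to the GFF3 1-based closed convention; CDS
#' phase is taken from the exons table.
#'
#' @param ann An `edc_annotation`.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(ann, path, source = "edcscan") {
  stopifnot(inherits(ann, "edc_annotation"))
  g <- ann$genes
  e <- ann$exons
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    ex <- e[e$gene == gi$gene, , drop = FALSE]
    ex <- ex[order(ex$exon_index), , drop = FALSE]
    attrs <- sprintf("ID=%s;family=%s;architecture=%s;status=%s",
                     gi$gene, gi$family, gi$architecture, gi$status)
    lines <- c(lines,
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
              gi$scaffold, source, gi$start + 1L, gi$end, gi$strand, attrs),
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              gi$scaffold, source, gi$start + 1L, gi$end, gi$strand,
              gi$gene, gi$gene))
    for (j in seq_len(nrow(ex))) {
      xj <- ex[j, ]
      lines <- c(lines,
        sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
                gi$scaffold, source, xj$start + 1L, xj$end, gi$strand, gi$gene))
      if (isTRUE(xj$coding)) {
        lines <- c(lines,
          sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s.t1",
                  gi$scaffold, source, xj$start + 1L, xj$end, gi$strand,
                  as.integer(xj$phase), gi$gene))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' Coordinates are converted back to the internal 0-based half-open
#' convention. Parsing uses rtracklayer when available and a minimal
#' column parser otherwise; both accept the dialect written by
#' [write_gff3()].
#'
#' @param path Path to a GFF3 file.
#' @return An `edc_annotation`.
#' @export
read_gff3 <- function(path) {
  .check(file.exists(path), sprintf("no such file: %s", path))
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr)
    df$attr_id <- if ("ID" %in% names(df)) df$ID else NA_character_
    df$attr_parent <- if ("Parent" %in% names(df)) {
      vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
    } else NA_character_
    raw <- data.frame(
      seqid = as.character(df$seqnames), type = as.character(df$type),
      start = df$start, end = df$end, strand = as.character(df$strand),
      phase = if ("phase" %in% names(df)) as.integer(as.character(df$phase)) else NA_integer_,
      id = df$attr_id, parent = df$attr_parent,
      family = if ("family" %in% names(df)) df$family else NA_character_,
      architecture = if ("architecture" %in% names(df)) df$architecture else NA_character_,
      status = if ("status" %in% names(df)) df$status else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    .check(all(lengths(f) == 9L), "malformed GFF3: expected 9 columns")
    f <- do.call(rbind, f)
    getattr <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
      vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
    }
    raw <- data.frame(
      seqid = f[, 1], type = f[, 3], start = as.integer(f[, 4]),
      end = as.integer(f[, 5]), strand = f[, 7],
      phase = suppressWarnings(as.integer(f[, 8])),
      id = getattr(f[, 9], "ID"), parent = getattr(f[, 9], "Parent"),
      family = getattr(f[, 9], "family"),
      architecture = getattr(f[, 9], "architecture"),
      status = getattr(f[, 9], "status"), stringsAsFactors = FALSE)
  }
  gr <- raw[raw$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene = gr$id, family = gr$family, architecture = gr$architecture,
    scaffold = gr$seqid, start = gr$start - 1L, end = gr$end,
    strand = gr$strand, status = gr$status, stringsAsFactors = FALSE)
  ex <- raw[raw$type == "exon", , drop = FALSE]
  cds <- raw[raw$type == "CDS", , drop = FALSE]
  ex$gene <- sub("\\.t1$", "", ex$parent)
  exons <- do.call(rbind, lapply(split(ex, ex$gene), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    key <- paste(d$start, d$end)
    cg <- cds[sub("\\.t1$", "", cds$parent) == d$gene[1], , drop = FALSE]
    ckey <- paste(cg$start, cg$end)
    data.frame(gene = d$gene, exon_index = seq_len(nrow(d)),
               start = d$start - 1L, end = d$end,
               coding = key %in% ckey,
               phase = cg$phase[match(key, ckey)],
               stringsAsFactors = FALSE)
  }))
  rownames(exons) <- NULL
  exons <- exons[order(match(exons$gene, genes$gene), exons$exon_index), ]
  edc_annotation(genes, exons)
}
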