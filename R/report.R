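# Pipeline orchestration: locate the anchored cluster region in a target
# genome, search every reference protein, rebuild gene models, call
# orthology, scan for lesions, profile proteins, and assemble the
# comparative family matrix.

#' Run the full cluster-annotation pipeline against a target genome
#'
#' The reference supplies intact gene templates (an `edc_cluster`, or any
#' list with `templates`, `truth`, `config`). The target is a scaffold set
#' (named character vector) or another `edc_cluster` (only its sequence is
#' used; its truth stays untouched for later evaluation).
#'
#' Steps: anchor proteins are searched first and the run aborts, naming
#' the anchor, if one is not found. Every reference protein is then
#' searched, its best locus chained, a template-guided model built,
#' lesions scanned against the template, and features profiled. Orthology
#' (reciprocal best hits + local synteny) is called between the reference
#' and the reconstructed annotation, and gene families are counted between
#' the anchors.
#'
#' @param ref Reference `edc_cluster`.
#' @param target Named character vector of scaffolds, or an `edc_cluster`.
#' @param params [search_params()] for the translated search.
#' @param max_intron Maximum intron length for HSP chaining (bp).
#' @param motif C-terminal motif pattern for SFTP profiling (default: the
#'   synthetic placeholder emitted by the generator).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List of class `edc_report`: `annotation` (reconstructed
#'   `edc_annotation`), `proteins`, `models`, `disruptions`,
#'   `orthology`, `features`, `family_matrix`, `manifest`.
#' @export
run_pipeline <- function(ref, target, params = search_params(),
                         max_intron = 10000L, motif = sftp_cterm_motif(),
                         seed = NA_integer_) {
  stopifnot(inherits(ref, "edc_cluster"))
  scaffolds <- if (inherits(target, "edc_cluster")) {
    stats::setNames(target$sequence, target$scaffold_id)
  } else target
  .check(!is.null(names(scaffolds)), "target scaffolds must be named")
  idx <- six_frame_index(scaffolds)
  anchors <- ref$config$anchor_names
  ref_genes <- ref$truth$genes

  # anchors first: abort naming the anchor if absent
  for (a in anchors) {
    h <- search_translated(
      stats::setNames(ref$templates[[a]]$protein, a), idx, params)
    if (nrow(h) == 0L || !length(chain_hsps(h, max_intron))) {
      stop(sprintf("anchor gene '%s' not found in target", a), call. = FALSE)
    }
  }

  # One-to-one assignment of loci to queries. Paralogous families (tandem
  # arrays, shared S100 domains, the conserved C-terminal motif) make a
  # query's single best chain unreliable, so loci are claimed iteratively:
  # each round the globally best remaining chain is assigned, and the
  # other queries re-chain with HSPs inside claimed regions removed.
  hsp_by_gene <- list()
  for (g in ref_genes$gene) {
    hsp_by_gene[[g]] <- search_translated(
      stats::setNames(ref$templates[[g]]$protein, g), idx, params)
  }
  assigned <- list()
  claimed <- data.frame(scaffold = character(0), start = integer(0),
                        end = integer(0))
  remaining <- ref_genes$gene
  repeat {
    if (!length(remaining)) break
    best <- NULL
    for (g in remaining) {
      h <- hsp_by_gene[[g]]
      if (nrow(h) && nrow(claimed)) {
        free <- vapply(seq_len(nrow(h)), function(i) {
          ov <- claimed$scaffold == h$scaffold_id[i] &
            pmin(claimed$end, h$gend[i]) - pmax(claimed$start, h$gstart[i]) >
              0.5 * (h$gend[i] - h$gstart[i])
          !any(ov)
        }, TRUE)
        h <- h[free, , drop = FALSE]
      }
      if (!nrow(h)) next
      loci <- chain_hsps(h, max_intron)
      if (!length(loci)) next
      l <- loci[[1]]
      if (is.null(best) || l$score > best$score) best <- c(l, list(gene = g))
    }
    if (is.null(best)) break
    assigned[[best$gene]] <- best
    claimed <- rbind(claimed, data.frame(
      scaffold = best$scaffold_id, start = best$start, end = best$end))
    remaining <- setdiff(remaining, best$gene)
  }
  unresolved <- setdiff(ref_genes$gene, names(assigned))

  models <- list()
  disruptions <- list()
  for (g in intersect(ref_genes$gene, names(assigned))) {
    tmpl <- exon_template(ref$templates[[g]])
    locus <- assigned[[g]]
    models[[g]] <- build_gene_model(locus, tmpl, scaffolds)
    disruptions[[g]] <- detect_disruptions(
      scaffolds,
      list(scaffold_id = locus$scaffold_id, start = locus$start,
           end = locus$end, strand = locus$strand),
      tmpl, margin = 800L)
  }

  # reconstructed annotation (coordinates from models, status from scans)
  rows <- lapply(names(models), function(g) {
    m <- models[[g]]
    data.frame(gene = g, family = ref_genes$family[ref_genes$gene == g],
               architecture = m$architecture, scaffold = m$scaffold_id,
               start = min(m$exons$start), end = max(m$exons$end),
               strand = m$strand, status = disruptions[[g]]$status,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genes <- genes[order(genes$scaffold, genes$start), , drop = FALSE]
  exons <- do.call(rbind, lapply(names(models), function(g) {
    m <- models[[g]]
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    data.frame(gene = g, exon_index = seq_len(nrow(ex)), start = ex$start,
               end = ex$end, coding = ex$coding, phase = ex$phase,
               stringsAsFactors = FALSE)
  }))
  annotation <- edc_annotation(genes, exons)
  proteins <- vapply(models, `[[`, "", "protein")

  # orthology between reference truth and the reconstruction
  ref_prot <- vapply(ref$templates[ref_genes$gene], `[[`, "", "protein")
  ortho <- call_orthologs(list(ann = ref$truth, proteins = ref_prot),
                          list(ann = annotation, proteins = proteins))

  # protein features
  features <- list(
    composition = composition_table(proteins[nchar(proteins) > 0]),
    motifs = do.call(rbind, lapply(names(proteins), function(g) {
      if (!nzchar(proteins[[g]])) return(NULL)
      mm <- scan_cterminal_motif(proteins[[g]], motif)
      data.frame(gene = g, found = mm$found, score = mm$score,
                 stringsAsFactors = FALSE)
    })))

  fam <- family_matrix(list(target = annotation), anchors)

  manifest <- list(
    seed = seed,
    anchors = anchors,
    reference_config = unclass(ref$config),
    search_params = params,
    max_intron = max_intron,
    motif = motif,
    n_target_scaffolds = length(scaffolds),
    target_bp = sum(nchar(scaffolds)),
    target_md5 = {
      tf <- tempfile(); writeLines(unlist(scaffolds), tf)
      unname(tools::md5sum(tf))
    },
    unresolved = unresolved)

  structure(list(annotation = annotation, proteins = proteins,
                 models = models, disruptions = disruptions,
                 orthology = ortho, features = features,
                 family_matrix = fam, manifest = manifest),
            class = "edc_report")
}

#' @export
print.edc_report <- function(x, ...) {
  cat("edc_report\n")
  print(x$annotation)
  st <- table(vapply(x$disruptions, `[[`, "", "status"))
  cat(sprintf("lesion scan: %s\n",
              paste(sprintf("%s=%d", names(st), as.integer(st)),
                    collapse = ", ")))
  if (length(x$manifest$unresolved)) {
    cat("unresolved genes:", paste(x$manifest$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count genes of one family between two anchor genes
#'
#' Counts genes strictly between the two anchors (which must lie on the
#' same scaffold) whose family matches, split into functional (status
#' intact or truncated; a truncated gene still encodes a shortened
#' protein) and pseudogene.
#'
#' @param ann An `edc_annotation` with status calls.
#' @param family Family label to count.
#' @param left_anchor,right_anchor Anchor gene names present in `ann`.
#' @return Named integer vector `c(functional = , pseudogene = )`.
#' @export
count_family_in_window <- function(ann, family, left_anchor, right_anchor) {
  g <- ann$genes
  la <- g[g$gene == left_anchor, ]
  ra <- g[g$gene == right_anchor, ]
  .check(nrow(la) == 1L && nrow(ra) == 1L, "anchors must be in the annotation")
  .check(la$scaffold == ra$scaffold,
         "anchors on different scaffolds: window undefined")
  lo <- min(la$end, ra$end); hi <- max(la$start, ra$start)
  win <- g[g$scaffold == la$scaffold & g$start >= lo & g$end <= hi &
             !(g$gene %in% c(left_anchor, right_anchor)), , drop = FALSE]
  win <- win[win$family == family, , drop = FALSE]
  c(functional = sum(win$status %in% c("intact", "truncated")),
    pseudogene = sum(win$status == "pseudogene"))
}

#' Family-by-species count matrix
#'
#' Rows are gene families, columns species; each cell is
#' "functional/pseudogene" counts between the anchors (anchor genes
#' themselves excluded).
#'
#' @param annotations Named list of `edc_annotation` objects (one per
#'   species).
#' @param anchors Pair of anchor gene names shared by all annotations.
#' @return Data frame with a `family` column and one column per species;
#'   attribute `counts` holds the underlying numeric array.
#' @export
family_matrix <- function(annotations, anchors) {
  fams <- sort(unique(unlist(lapply(annotations, function(a) {
    setdiff(a$genes$family, "anchor")
  }))))
  counts <- array(0L, dim = c(length(fams), length(annotations), 2L),
                  dimnames = list(fams, names(annotations),
                                  c("functional", "pseudogene")))
  out <- data.frame(family = fams, stringsAsFactors = FALSE)
  for (sp in names(annotations)) {
    cells <- vapply(fams, function(f) {
      ct <- count_family_in_window(annotations[[sp]], f, anchors[1], anchors[2])
      counts[f, sp, ] <<- ct
      sprintf("%d/%d", ct["functional"], ct["pseudogene"])
    }, "")
    out[[sp]] <- cells
  }
  attr(out, "counts") <- counts
  out
}

#' Write a report bundle to a directory
#'
#' Emits the reconstructed annotation (GFF3 + genes TSV), proteins FASTA,
#' orthology TSV, lesion TSV, composition and motif TSVs, the family
#' matrix TSV and the JSON manifest.
#'
#' @param report An `edc_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gff3(report$annotation, file.path(dir, "annotation.gff3"))
  utils::write.table(report$annotation$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- nchar(report$proteins) > 0
  if (any(keep)) write_fasta(report$proteins[keep],
                             file.path(dir, "proteins.faa"))
  utils::write.table(report$orthology, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_lesion_tsv(report$disruptions, file.path(dir, "lesions.tsv"),
                   scaffold_id = report$annotation$genes$scaffold[1])
  utils::write.table(report$features$composition,
                     file.path(dir, "composition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$features$motifs, file.path(dir, "motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$family_matrix, file.path(dir, "family_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
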