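# Synthetic EDC-like cluster generator. Produces a scaffold carrying an
# ordered, anchored gene cluster with known gene models (a machine-readable
# truth table), tandem-amplified paralog arrays with their true genealogy,
# and implanted inactivating lesions. This is the desk-scale test bed for
# every downstream stage of the pipeline.
#
# Conventions: gene units are built on the sense (transcribed) strand with
# local 0-based half-open exon coordinates; assembly places units on either
# scaffold strand and converts to scaffold coordinates. All randomness runs
# through one seeded RNG (with_seed), so a config reproduces byte-identical
# output.

# Synthetic S100-like domain consensus (90 residues). This is an invented
# sequence with the length and N-terminal placement of an S100 domain; it is
# NOT a real protein. It seeds both the generator (anchor genes and SFTP
# N-termini are diverged copies) and the packaged consensus profile used for
# architecture classification.
.S100_CONSENSUS <- paste0(
  "MTELETAMGM", "IIDVFSRYSG", "SEGSTQTLTK", "GELKVLMEKE", "LPGFLQSGKD",
  "KDAVDKLLKD", "LDANGDAQVD", "FSEFIVFVAA", "ITSACHKYFE")

# Synthetic placeholder for the conserved SFTP C-terminal motif. The real
# motif is not modelled; this constant exists so motif scanning has a known
# ground truth in synthetic proteins.
.SFTP_CTERM_MOTIF <- "KQDYWESH"

#' Synthetic S100-domain consensus and C-terminal motif placeholder
#'
#' Accessors for the package's bundled synthetic sequences: the 90-residue
#' S100-like domain consensus used by the generator and the architecture
#' classifier, and the placeholder C-terminal motif appended to intact
#' synthetic SFTP proteins. Both are invented sequences, not real biology.
#'
#' @return A character scalar.
#' @export
s100_consensus <- function() .S100_CONSENSUS

#' @rdname s100_consensus
#' @export
sftp_cterm_motif <- function() .SFTP_CTERM_MOTIF

# residue -> codons lookup (sense codons only)
.aa_codons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- .codon_table()
      tab <<- split(names(gc), gc)
    }
    tab
  }
})

.BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.random_protein <- function(n, bias_residues = NULL, bias_frac = 0.75) {
  aa <- setdiff(names(.aa_codons()), "*")
  if (is.null(bias_residues)) {
    paste(sample(aa, n, replace = TRUE), collapse = "")
  } else {
    pick_bias <- runif(n) < bias_frac
    res <- character(n)
    res[pick_bias] <- sample(bias_residues, sum(pick_bias), replace = TRUE)
    res[!pick_bias] <- sample(aa, sum(!pick_bias), replace = TRUE)
    paste(res, collapse = "")
  }
}

# reverse-translate a protein with uniformly sampled synonymous codons
.rev_translate <- function(protein) {
  map <- .aa_codons()
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(a) {
    cs <- map[[a]]
    if (is.null(cs)) stop(sprintf("cannot reverse-translate residue '%s'", a))
    cs[sample.int(length(cs), 1L)]
  }, "")
  paste(codons, collapse = "")
}

# per-site substitution at `rate`; unconstrained
.mutate_dna <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate & ch %in% .BASES)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

.mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aa <- setdiff(names(.aa_codons()), "*")
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  hit <- setdiff(hit, 1L)  # keep the initiator residue
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1L)
  paste(ch, collapse = "")
}

# per-site substitution over a CDS that preserves coding capacity: the first
# (ATG) and final (stop) codons are untouched and any substitution that
# creates an internal in-frame stop is reverted, so lesion status stays the
# exclusive product of implant_lesion().
.mutate_cds_safe <- function(cds, rate) {
  if (rate <= 0) return(cds)
  n <- nchar(cds)
  ch <- strsplit(cds, "", fixed = TRUE)[[1]]
  orig <- ch
  hit <- which(runif(n) < rate)
  hit <- hit[hit > 3L & hit <= n - 3L]
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  mut <- paste(ch, collapse = "")
  codons <- .codons(mut)
  bad <- which(codons %in% .STOPS)
  bad <- bad[bad < length(codons)]
  for (b in bad) {
    idx <- (b - 1L) * 3L + 1:3
    ch[idx] <- orig[idx]
  }
  paste(ch, collapse = "")
}

# ---------------------------------------------------------------------------
# gene units

.intron <- function(len) {
  len <- max(len, 8L)
  paste0("GT", .random_dna(len - 4L), "AG")
}

.unit_from_parts <- function(name, family, architecture, parts) {
  # parts: list of list(seq=, coding=)
  lens <- vapply(parts, function(p) nchar(p$seq), 0L)
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  coding <- vapply(parts, function(p) isTRUE(p$coding), TRUE)
  exonic <- vapply(parts, function(p) !isTRUE(p$intron), TRUE)
  ex <- data.frame(start = starts[exonic], end = ends[exonic],
                   coding = coding[exonic])
  cdslen <- cumsum(ifelse(ex$coding, ex$end - ex$start, 0L))
  before <- c(0L, cdslen[-nrow(ex)])
  ex$phase <- ifelse(ex$coding, (3L - before %% 3L) %% 3L, NA_integer_)
  dna <- paste(vapply(parts, function(p) p$seq, ""), collapse = "")
  cds <- paste(vapply(parts[coding & exonic], function(p) p$seq, ""),
               collapse = "")
  protein <- sub("\\*$", "", translate_dna(cds, 0L, "+"))
  list(name = name, family = family, architecture = architecture,
       dna = dna, exons = ex, cds = cds, protein = protein)
}

.make_sedc_unit <- function(name, family = "SEDC", body_protein = NULL,
                            n_codons = NULL, bias = NULL) {
  if (is.null(body_protein)) {
    if (is.null(n_codons)) n_codons <- sample(80:200, 1L)
    body_protein <- .random_protein(n_codons, bias_residues = bias,
                                    bias_frac = 0.6)
  }
  cds <- paste0("ATG", .rev_translate(body_protein),
                sample(.STOPS, 1L))
  parts <- list(
    list(seq = .random_dna(sample(80:150, 1L)), coding = FALSE),
    list(seq = .intron(sample(150:400, 1L)), coding = FALSE, intron = TRUE),
    list(seq = cds, coding = TRUE))
  .unit_from_parts(name, family, "SEDC", parts)
}

.make_anchor_unit <- function(name) {
  dom <- .mutate_protein(.S100_CONSENSUS, 0.08)
  u <- .make_sedc_unit(name, family = "anchor",
                       body_protein = substring(dom, 2L))
  u$architecture <- "SEDC"
  u
}

# SFTP-like: non-coding exon, coding exon carrying the S100-like domain,
# coding exon carrying a repetitive composition-biased tail ending in the
# C-terminal motif placeholder. The whole domain sits in the first coding
# exon so that architecture classification can test the first coding
# segment against the packaged consensus.
.make_sftp_unit <- function(name, bias = c("R", "E"), unit_len = NULL,
                            n_copies = NULL, copy_sub = 0.05) {
  dom <- .mutate_protein(.S100_CONSENSUS, 0.08)
  exon2 <- .rev_translate(dom)  # starts with ATG via consensus M
  if (is.null(unit_len)) unit_len <- sample(9:21, 1L)
  if (is.null(n_copies)) n_copies <- sample(8:20, 1L)
  # fix the biased-position count exactly (short units would otherwise
  # drift far from the configured composition) and keep per-copy
  # substitutions composition-preserving by drawing replacements from the
  # same biased distribution
  aa <- setdiff(names(.aa_codons()), "*")
  n_bias <- round(0.78 * unit_len)
  uch <- character(unit_len)
  at <- sample.int(unit_len, n_bias)
  uch[at] <- sample(bias, n_bias, replace = TRUE)
  uch[-at] <- sample(setdiff(aa, bias), unit_len - n_bias, replace = TRUE)
  unit <- paste(uch, collapse = "")
  biased_draw <- function(exclude) {
    repeat {
      r <- if (runif(1) < 0.78) sample(bias, 1L) else sample(aa, 1L)
      if (r != exclude) return(r)
    }
  }
  copies <- vapply(seq_len(n_copies), function(i) {
    ch <- strsplit(unit, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < copy_sub)
    for (j in hit) ch[j] <- biased_draw(ch[j])
    paste(ch, collapse = "")
  }, "")
  tail_prot <- paste0(paste(copies, collapse = ""), .SFTP_CTERM_MOTIF)
  exon3 <- paste0(.rev_translate(tail_prot), sample(.STOPS, 1L))
  parts <- list(
    list(seq = .random_dna(sample(80:150, 1L)), coding = FALSE),
    list(seq = .intron(sample(150:400, 1L)), coding = FALSE, intron = TRUE),
    list(seq = exon2, coding = TRUE),
    list(seq = .intron(sample(150:400, 1L)), coding = FALSE, intron = TRUE),
    list(seq = exon3, coding = TRUE))
  u <- .unit_from_parts(name, "SFTP", "SFTP", parts)
  u$repeat_unit_len <- unit_len
  u$repeat_copies <- n_copies
  u$tail_bias <- bias
  u
}

# mutate a whole gene unit at `rate` while preserving coding capacity and
# splice dinucleotides; used for tandem copies and sister-species divergence
.mutate_unit <- function(unit, rate) {
  ex <- unit$exons
  dna <- unit$dna
  n <- nchar(dna)
  # classify each position: coding exon, non-coding exon, intron
  segs <- list()
  bounds <- sort(unique(c(0L, ex$start, ex$end, n)))
  out <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    piece <- substr(dna, a + 1L, b)
    row <- which(ex$start == a & ex$end == b)
    if (length(row) == 1L && ex$coding[row]) {
      out <- c(out, piece)  # handled jointly below via CDS
    } else if (length(row) == 1L) {
      out <- c(out, .mutate_dna(piece, rate))
    } else {
      # intron: keep GT...AG
      if (nchar(piece) > 4L) {
        mid <- .mutate_dna(substr(piece, 3L, nchar(piece) - 2L), rate)
        out <- c(out, paste0(substr(piece, 1L, 2L), mid,
                             substr(piece, nchar(piece) - 1L, nchar(piece))))
      } else out <- c(out, piece)
    }
  }
  # mutate the CDS as one frame-safe unit, then redistribute over exons
  cds_mut <- .mutate_cds_safe(unit$cds, rate)
  cds_pos <- 0L
  pieces <- out
  k <- 0L
  for (i in seq_len(length(bounds) - 1L)) {
    k <- k + 1L
    a <- bounds[i]; b <- bounds[i + 1L]
    row <- which(ex$start == a & ex$end == b)
    if (length(row) == 1L && ex$coding[row]) {
      len <- b - a
      pieces[k] <- substr(cds_mut, cds_pos + 1L, cds_pos + len)
      cds_pos <- cds_pos + len
    }
  }
  u <- unit
  u$dna <- paste(pieces, collapse = "")
  u$cds <- cds_mut
  u$protein <- sub("\\*$", "", translate_dna(cds_mut, 0L, "+"))
  u
}

# ---------------------------------------------------------------------------
# tandem amplification

# Forward-time duplication genealogy: at each event a uniformly chosen
# existing lineage bifurcates (the continuing lineage keeps its label, the
# new copy gets the next label). Node heights are event indices and every
# leaf extends to the final event time, so the genealogy is ultrametric in
# duplication-event count. Returns a newick string (or a bare label for a
# single copy).
.duplication_genealogy <- function(n_copies, labels) {
  if (n_copies == 1L) return(labels[1])
  born <- c(node1 = 0L)
  split_time <- c(node1 = NA_integer_)
  children <- list(node1 = NULL)
  label <- c(node1 = labels[1])
  active <- "node1"
  next_id <- 2L
  for (t in seq_len(n_copies - 1L)) {
    x <- active[sample.int(length(active), 1L)]
    y <- sprintf("node%d", next_id); next_id <- next_id + 1L
    z <- sprintf("node%d", next_id); next_id <- next_id + 1L
    born[c(y, z)] <- t
    split_time[c(y, z)] <- NA_integer_
    children[[y]] <- NULL; children[[z]] <- NULL
    split_time[x] <- t
    children[[x]] <- c(y, z)
    label[y] <- label[x]              # continuing lineage keeps its label
    label[z] <- labels[t + 1L]        # new copy
    label[x] <- NA_character_
    active <- c(setdiff(active, x), y, z)
  }
  t_final <- n_copies - 1L
  rec <- function(id) {
    ch <- children[[id]]
    if (is.null(ch)) {
      sprintf("%s:%d", label[id], t_final - born[id])
    } else {
      sprintf("(%s,%s):%d", rec(ch[1]), rec(ch[2]),
              split_time[id] - born[id])
    }
  }
  ch <- children[["node1"]]
  sprintf("(%s,%s)", rec(ch[1]), rec(ch[2]))
}

#' Simulate tandem amplification of a founder sequence
#'
#' Grows an array of `n_copies` by iterated duplication of a uniformly
#' chosen existing copy (the mechanism of unequal crossing over produces
#' exactly this kind of nested duplication history), then applies per-site
#' substitution at rate `divergence` to every copy. The true genealogy is
#' returned as an `ape` tree in which the copies form a clade relative to
#' any supplied outgroup sequences; branch lengths count duplication events
#' (the genealogy is ultrametric over the copies).
#'
#' @param founder_seq DNA string: the founder repeat unit (a CDS or a whole
#'   gene region).
#' @param n_copies Number of copies in the final array (>= 1).
#' @param divergence Per-site substitution probability applied to each copy.
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param outgroups Optional named character vector of outgroup sequences;
#'   they are attached outside the copy clade in the genealogy and appended
#'   after the array in `$sequences`.
#' @param frame_safe If TRUE, `founder_seq` is treated as an in-frame CDS
#'   and substitutions that would create an internal stop codon are
#'   redrawn, so copies stay translatable.
#' @return List with `copies` (named character vector copy1..copyN),
#'   `sequence` (the concatenated array), `tree` (an `ape::phylo`, or the
#'   single leaf label when there is only one leaf in total), and
#'   `copy_labels`.
#' @export
amplify_tandem <- function(founder_seq, n_copies, divergence, seed,
                           outgroups = NULL, frame_safe = FALSE) {
  .check(n_copies >= 1L, "n_copies must be >= 1")
  .check(divergence >= 0 && divergence <= 0.5,
         "divergence must be in [0, 0.5]")
  with_seed(seed, {
    labels <- sprintf("copy%d", seq_len(n_copies))
    nwk_core <- .duplication_genealogy(n_copies, labels)
    mut <- if (frame_safe) .mutate_cds_safe else .mutate_dna
    copies <- vapply(seq_len(n_copies), function(i) mut(founder_seq, divergence), "")
    names(copies) <- labels
    nwk <- if (is.null(outgroups)) {
      if (n_copies == 1L) labels[1] else paste0(nwk_core, ";")
    } else {
      core <- if (n_copies == 1L) sprintf("%s:1", labels[1])
              else sprintf("%s:1", nwk_core)
      ogs <- paste(sprintf("%s:1", names(outgroups)), collapse = ",")
      sprintf("(%s,%s);", core, ogs)
    }
    tree <- if (grepl(";", nwk, fixed = TRUE)) ape::read.tree(text = nwk) else nwk
    list(copies = copies, sequence = paste(copies, collapse = ""),
         tree = tree, copy_labels = labels)
  })
}

# ---------------------------------------------------------------------------
# cluster configuration and generation

#' Configuration for a synthetic EDC-like cluster
#'
#' Defaults describe a desk-scale cluster: a handful of single-coding-exon
#' (SEDC-like) genes, a few two-coding-exon genes with an S100-like domain
#' and a composition-biased repetitive tail (SFTP-like), a tandem-amplified
#' near-identical array (LCE-like), and two flanking anchor genes.
#'
#' @param seed Integer seed; all generation randomness derives from it.
#' @param n_sedc Number of generic SEDC-like genes.
#' @param n_sftp Number of SFTP-like genes.
#' @param lce_array_size Number of copies in the LCE-like tandem array.
#' @param lce_divergence Per-site substitution rate among array copies,
#'   in [0, 0.5].
#' @param lesion_rate Probability that a non-anchor gene receives one
#'   implanted inactivating lesion.
#' @param intergenic_mean Mean intergenic spacer length in bp (geometric).
#' @param anchor_names Labels of the two flanking anchor genes.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(seed = 1L, n_sedc = 6L, n_sftp = 3L,
                           lce_array_size = 8L, lce_divergence = 0.02,
                           lesion_rate = 0, intergenic_mean = 1000L,
                           anchor_names = c("S100A9", "S100A11")) {
  .check(all(c(n_sedc, n_sftp, lce_array_size) >= 0L), "counts must be >= 0")
  .check(lce_divergence >= 0 && lce_divergence <= 0.5,
         "lce_divergence must be in [0, 0.5]")
  .check(lesion_rate >= 0 && lesion_rate <= 1, "lesion_rate must be in [0, 1]")
  .check(length(anchor_names) == 2L, "anchor_names must be a pair")
  structure(list(seed = as.integer(seed), n_sedc = as.integer(n_sedc),
                 n_sftp = as.integer(n_sftp),
                 lce_array_size = as.integer(lce_array_size),
                 lce_divergence = lce_divergence, lesion_rate = lesion_rate,
                 intergenic_mean = as.integer(intergenic_mean),
                 anchor_names = anchor_names),
            class = "cluster_config")
}

.LESION_KINDS <- c("premature_stop", "frameshift_ins", "frameshift_del",
                   "splice_loss", "exon_deletion")

.empty_lesions <- function() {
  data.frame(gene = character(0), kind = character(0),
             genomic_pos = integer(0), codon_index = integer(0),
             detail = character(0), stringsAsFactors = FALSE)
}

# assemble gene units (sense-strand) into a scaffold + truth annotation
.assemble_cluster <- function(units, strands, spacers, scaffold_id) {
  n <- length(units)
  .check(length(strands) == n && length(spacers) == n + 1L,
         "assembly inputs inconsistent")
  chunks <- character(2L * n + 1L)
  genes <- vector("list", n)
  exlist <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    chunks[2L * i - 1L] <- spacers[i]
    pos <- pos + nchar(spacers[i])
    u <- units[[i]]
    L <- nchar(u$dna)
    gstart <- pos
    gend <- pos + L
    chunks[2L * i] <- if (strands[i] == "+") u$dna else reverse_complement(u$dna)
    ex <- u$exons
    if (strands[i] == "+") {
      gs <- gstart + ex$start; ge <- gstart + ex$end
    } else {
      gs <- gstart + (L - ex$end); ge <- gstart + (L - ex$start)
    }
    exg <- data.frame(gene = u$name, exon_index = NA_integer_,
                      start = gs, end = ge, coding = ex$coding,
                      phase = ex$phase, stringsAsFactors = FALSE)
    exg <- exg[order(exg$start), , drop = FALSE]
    exg$exon_index <- seq_len(nrow(exg))
    exlist[[i]] <- exg
    genes[[i]] <- data.frame(
      gene = u$name, family = u$family, architecture = u$architecture,
      scaffold = scaffold_id, start = gstart, end = gend,
      strand = strands[i], status = "intact", stringsAsFactors = FALSE)
    pos <- gend
  }
  chunks[2L * n + 1L] <- spacers[n + 1L]
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exlist)
  rownames(genes) <- rownames(exons) <- NULL
  list(sequence = paste(chunks, collapse = ""),
       truth = edc_annotation(genes, exons))
}

#' Generate a synthetic EDC-like cluster with truth table
#'
#' Builds a scaffold carrying, in order: the left anchor, SEDC-like genes,
#' SFTP-like genes, more SEDC-like genes, an LCE-like tandem array (grown by
#' iterated duplication) and the right anchor, separated by random
#' intergenic spacers with geometric lengths. Genes land on both strands.
#' With `lesion_rate > 0`, non-anchor genes receive implanted inactivating
#' lesions; every lesion and the resulting true status is recorded in the
#' truth tables. Intact pre-lesion gene units are kept as templates.
#'
#' @param config A [cluster_config()].
#' @param scaffold_id Name of the generated scaffold.
#' @return An object of class `edc_cluster`: list with `scaffold_id`,
#'   `sequence`, `truth` (an `edc_annotation`), `lesions` (truth lesion
#'   table), `templates` (named list of intact sense-strand gene units),
#'   `genealogy` (true LCE-array genealogy) and `config`.
#' @export
generate_cluster <- function(config, scaffold_id = "synthEDC") {
  stopifnot(inherits(config, "cluster_config"))
  with_seed(config$seed, {
    units <- list()
    add <- function(u) units[[length(units) + 1L]] <<- u
    add(.make_anchor_unit(config$anchor_names[1]))
    n1 <- ceiling(config$n_sedc / 2)
    for (i in seq_len(n1)) add(.make_sedc_unit(sprintf("SEDC%d", i)))
    for (i in seq_len(config$n_sftp)) {
      bias <- if (i %% 2L == 1L) c("R", "E") else c("G", "S")
      add(.make_sftp_unit(sprintf("SFTP%d", i), bias = bias))
    }
    for (i in seq.int(n1 + 1L, length.out = config$n_sedc - n1)) {
      add(.make_sedc_unit(sprintf("SEDC%d", i)))
    }
    genealogy <- NULL
    if (config$lce_array_size > 0L) {
      founder <- .make_sedc_unit("LCEfounder", family = "LCE-like",
                                 n_codons = sample(100:130, 1L),
                                 bias = c("C", "Q", "K", "P"))
      amp_seed <- sample.int(.Machine$integer.max, 1L)
      amp <- amplify_tandem(founder$cds, config$lce_array_size,
                            config$lce_divergence, seed = amp_seed,
                            frame_safe = TRUE)
      genealogy <- amp$tree
      for (i in seq_len(config$lce_array_size)) {
        u <- founder
        u$name <- sprintf("LCE%d", i)
        cds <- amp$copies[[i]]
        # swap the copy CDS into the founder unit
        ce <- which(u$exons$coding)
        pre <- substr(u$dna, 1L, u$exons$start[ce])
        u$dna <- paste0(pre, cds)
        u$exons$end[ce] <- u$exons$start[ce] + nchar(cds)
        u$cds <- cds
        u$protein <- sub("\\*$", "", translate_dna(cds, 0L, "+"))
        if (!is.null(genealogy) && inherits(genealogy, "phylo")) {
          genealogy$tip.label[genealogy$tip.label == sprintf("copy%d", i)] <-
            u$name
        }
        add(u)
      }
    }
    add(.make_anchor_unit(config$anchor_names[2]))

    n <- length(units)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    if (length(unique(strands)) == 1L && n > 2L) {
      strands[2L] <- setdiff(c("+", "-"), strands[1])
    }
    spacers <- vapply(seq_len(n + 1L), function(i) {
      .random_dna(50L + stats::rgeom(1L, 1 / max(config$intergenic_mean - 50L, 1L)))
    }, "")
    total <- sum(vapply(units, function(u) nchar(u$dna), 0L)) +
      sum(nchar(spacers))
    .check(total <= 10e6, "configuration would produce a scaffold > 10 Mbp")

    asm <- .assemble_cluster(units, strands, spacers, scaffold_id)
    templates <- stats::setNames(units, vapply(units, `[[`, "", "name"))
    cluster <- structure(
      list(scaffold_id = scaffold_id, sequence = asm$sequence,
           truth = asm$truth, lesions = .empty_lesions(),
           templates = templates, genealogy = genealogy, config = config),
      class = "edc_cluster")

    if (config$lesion_rate > 0) {
      targets <- cluster$truth$genes$gene[cluster$truth$genes$family != "anchor"]
      hit <- targets[stats::runif(length(targets)) < config$lesion_rate]
      for (g in hit) {
        kind <- .sample_lesion_kind(cluster, g)
        cluster <- implant_lesion(cluster, g, kind)
      }
    }
    cluster$truth$genes$status <- vapply(cluster$truth$genes$gene, function(g) {
      .status_from_lesions(cluster$lesions[cluster$lesions$gene == g, , drop = FALSE],
                           nchar(cluster$templates[[g]]$protein) + 1L)
    }, "")
    cluster
  })
}

.sample_lesion_kind <- function(cluster, gene) {
  ex <- cluster$truth$exons
  n_coding <- sum(ex$coding[ex$gene == gene])
  repeat {
    kind <- sample(.LESION_KINDS, 1L,
                   prob = c(0.35, 0.2, 0.2, 0.15, 0.1))
    if (kind != "exon_deletion" || n_coding >= 2L) return(kind)
  }
}

#' @export
print.edc_cluster <- function(x, ...) {
  cat(sprintf("edc_cluster '%s': %d bp, %d genes, %d implanted lesions\n",
              x$scaffold_id, nchar(x$sequence), nrow(x$truth$genes),
              nrow(x$lesions)))
  print(x$truth)
  invisible(x)
}

# ---------------------------------------------------------------------------
# lesion implantation

# sense-local exon table for one gene (start/end relative to gene start in
# transcription orientation), with cumulative CDS offsets
.sense_exons <- function(cluster, gene) {
  g <- cluster$truth$genes[cluster$truth$genes$gene == gene, ]
  .check(nrow(g) == 1L, sprintf("unknown gene '%s'", gene))
  ex <- cluster$truth$exons[cluster$truth$exons$gene == gene, , drop = FALSE]
  if (g$strand == "+") {
    s <- ex$start - g$start; e <- ex$end - g$start
  } else {
    s <- g$end - ex$end; e <- g$end - ex$start
  }
  o <- order(s)
  out <- data.frame(start = s[o], end = e[o], coding = ex$coding[o],
                    phase = ex$phase[o])
  cds_len <- ifelse(out$coding, out$end - out$start, 0L)
  out$cds_before <- c(0L, cumsum(cds_len))[seq_len(nrow(out))]
  attr(out, "gene_row") <- g
  out
}

# scaffold coordinate of a sense-local span [p, p+len) of a gene
.sense_to_scaffold <- function(g, p, len = 1L) {
  if (g$strand == "+") g$start + p else g$end - p - len
}

# apply a replacement edit to the scaffold: remove k bases at 0-based `at`,
# insert `ins`; shift all stored coordinates accordingly
.apply_edit <- function(cluster, at, k, ins) {
  seq <- cluster$sequence
  n <- nchar(seq)
  .check(at >= 0 && at + k <= n, "edit outside scaffold")
  cluster$sequence <- paste0(substr(seq, 1L, at), ins,
                             substr(seq, at + k + 1L, n))
  delta <- nchar(ins) - k
  if (delta != 0L) {
    shift <- function(x) ifelse(x >= at + k, x + delta, x)
    cluster$truth$genes$start <- shift(cluster$truth$genes$start)
    cluster$truth$genes$end <- shift(cluster$truth$genes$end)
    cluster$truth$exons$start <- shift(cluster$truth$exons$start)
    cluster$truth$exons$end <- shift(cluster$truth$exons$end)
    if (nrow(cluster$lesions)) {
      cluster$lesions$genomic_pos <- shift(cluster$lesions$genomic_pos)
    }
  }
  cluster
}

# current sense-strand sequence of a gene
.gene_sense_seq <- function(cluster, g) {
  s <- substr(cluster$sequence, g$start + 1L, g$end)
  if (g$strand == "-") reverse_complement(s) else s
}

# Shift an indel block left to its canonical (leftmost equivalent) position
# within `seq`, the same normalization convention used for VCF indels.
# Lesion coordinates are normalized in gene sense space (for insertions on
# the mutated sequence, for deletions on the pre-deletion sequence), which
# the lesion scanner can reproduce from the intact template. [a, a+len) is
# the 0-based block; returns the normalized a.
.normalize_indel_left <- function(seq, a, len, floor_pos = 0L) {
  while (a > floor_pos &&
         substr(seq, a, a) == substr(seq, a + len, a + len)) {
    a <- a - 1L
  }
  a
}

#' Implant an inactivating lesion into a synthetic cluster gene
#'
#' Mutates the scaffold in place: a premature stop substitutes one in-frame
#' codon with TAA/TAG/TGA; a frameshift inserts or deletes 1-2 bp inside a
#' coding exon; splice loss mutates one base of an intron's GT donor or AG
#' acceptor; exon deletion removes one coding exon. All truth coordinates
#' downstream of a length-changing edit are shifted, and the lesion is
#' appended to the truth lesion table with its canonical (left-normalized)
#' forward-strand coordinate.
#'
#' @param cluster An `edc_cluster`.
#' @param gene Gene name in the truth table.
#' @param kind One of premature_stop, frameshift_ins, frameshift_del,
#'   splice_loss, exon_deletion.
#' @param position For premature_stop: 1-based codon index; for
#'   frameshift_*: 0-based CDS nucleotide offset; for exon_deletion: coding
#'   exon number (in transcription order); NULL samples a valid position
#'   from the current RNG stream.
#' @return The mutated `edc_cluster`.
#' @export
implant_lesion <- function(cluster, gene, kind, position = NULL) {
  stopifnot(inherits(cluster, "edc_cluster"))
  kind <- match.arg(kind, .LESION_KINDS)
  ex <- .sense_exons(cluster, gene)
  g <- attr(ex, "gene_row")
  cod <- ex[ex$coding, , drop = FALSE]
  cds_len <- sum(cod$end - cod$start)
  n_codons <- cds_len %/% 3L
  # map a CDS offset to a sense-local gene position
  cds_to_sense <- function(o) {
    for (i in seq_len(nrow(cod))) {
      w <- cod$end[i] - cod$start[i]
      if (o < cod$cds_before[i] + w) return(cod$start[i] + (o - cod$cds_before[i]))
    }
    stop("CDS offset outside gene")
  }
  same_exon <- function(o, k) {
    for (i in seq_len(nrow(cod))) {
      w <- cod$end[i] - cod$start[i]
      if (o >= cod$cds_before[i] && o + k <= cod$cds_before[i] + w) return(TRUE)
    }
    FALSE
  }
  les <- NULL
  if (kind == "premature_stop") {
    ci <- if (!is.null(position)) as.integer(position) else {
      lo <- max(5L, ceiling(0.1 * n_codons))
      hi <- min(n_codons - 2L, floor(0.9 * n_codons))
      sample(seq.int(lo, hi), 1L)
    }
    .check(ci >= 2L && ci < n_codons, "codon index outside coding region")
    o <- (ci - 1L) * 3L
    .check(same_exon(o, 3L), "codon spans an exon boundary")
    p <- cds_to_sense(o)
    at <- .sense_to_scaffold(g, p, 3L)
    stop_codon <- sample(.STOPS, 1L)
    ins <- if (g$strand == "+") stop_codon else reverse_complement(stop_codon)
    cluster <- .apply_edit(cluster, at, 3L, ins)
    les <- data.frame(gene = gene, kind = "premature_stop",
                      genomic_pos = at, codon_index = ci,
                      detail = stop_codon, stringsAsFactors = FALSE)
  } else if (kind %in% c("frameshift_ins", "frameshift_del")) {
    k <- sample(1:2, 1L)
    o <- if (!is.null(position)) as.integer(position) else {
      repeat {
        o <- sample(seq.int(3L, cds_len - 6L), 1L)
        if (same_exon(o, k)) break
      }
      o
    }
    .check(o >= 3L && o + k <= cds_len - 3L && same_exon(o, k),
           "frameshift position outside a single coding exon")
    p <- cds_to_sense(o)
    sense <- .gene_sense_seq(cluster, g)
    if (kind == "frameshift_ins") {
      ins <- .random_dna(k)
      sense_mut <- paste0(substr(sense, 1L, p), ins,
                          substr(sense, p + 1L, nchar(sense)))
      pn <- .normalize_indel_left(sense_mut, p, k)
      at <- if (g$strand == "+") g$start + pn else g$end - pn
      s_ins <- if (g$strand == "+") substr(sense_mut, pn + 1L, pn + k)
               else reverse_complement(substr(sense_mut, pn + 1L, pn + k))
      cluster <- .apply_edit(cluster, at, 0L, s_ins)
      les <- data.frame(gene = gene, kind = "frameshift_ins",
                        genomic_pos = at, codon_index = o %/% 3L + 1L,
                        detail = sprintf("ins%d", k), stringsAsFactors = FALSE)
    } else {
      pn <- .normalize_indel_left(sense, p, k)
      at <- .sense_to_scaffold(g, pn, k)
      cluster <- .apply_edit(cluster, at, k, "")
      les <- data.frame(gene = gene, kind = "frameshift_del",
                        genomic_pos = at, codon_index = o %/% 3L + 1L,
                        detail = sprintf("del%d", k), stringsAsFactors = FALSE)
    }
  } else if (kind == "splice_loss") {
    introns <- data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
    introns <- introns[introns$end > introns$start, , drop = FALSE]
    .check(nrow(introns) >= 1L, "gene has no intron")
    i <- if (!is.null(position)) as.integer(position)
         else sample.int(nrow(introns), 1L)
    side <- sample(c("donor", "acceptor"), 1L)
    if (side == "donor") {
      p <- introns$start[i]  # the G of GT
      old <- "G"; new <- sample(c("A", "C", "T"), 1L)
      detail <- sprintf("donor GT>%sT", new)
    } else {
      p <- introns$end[i] - 1L  # the G of AG
      old <- "G"; new <- sample(c("A", "C", "T"), 1L)
      detail <- sprintf("acceptor AG>A%s", new)
    }
    at <- .sense_to_scaffold(g, p, 1L)
    ins <- if (g$strand == "+") new else chartr("ACGT", "TGCA", new)
    cluster <- .apply_edit(cluster, at, 1L, ins)
    les <- data.frame(gene = gene, kind = "splice_loss", genomic_pos = at,
                      codon_index = NA_integer_, detail = detail,
                      stringsAsFactors = FALSE)
  } else if (kind == "exon_deletion") {
    idx <- which(ex$coding)
    .check(length(idx) >= 2L, "exon_deletion requires >= 2 coding exons")
    j <- if (!is.null(position)) idx[as.integer(position)]
         else idx[sample.int(length(idx), 1L)]
    p0 <- ex$start[j]; p1 <- ex$end[j]
    sense <- .gene_sense_seq(cluster, g)
    p0n <- .normalize_indel_left(sense, p0, p1 - p0)
    at <- .sense_to_scaffold(g, p0n, p1 - p0)
    ci <- ex$cds_before[j] %/% 3L + 1L
    # drop the exon row from the truth before shifting
    te <- cluster$truth$exons
    drop <- te$gene == gene &
      ((g$strand == "+" & te$start == g$start + p0) |
       (g$strand == "-" & te$end == g$end - p0))
    cluster$truth$exons <- te[!drop, , drop = FALSE]
    cluster <- .apply_edit(cluster, at, p1 - p0, "")
    ei <- cluster$truth$exons$gene == gene
    cluster$truth$exons$exon_index[ei] <-
      rank(cluster$truth$exons$start[ei])
    les <- data.frame(gene = gene, kind = "exon_deletion", genomic_pos = at,
                      codon_index = ci,
                      detail = sprintf("len%d", p1 - p0),
                      stringsAsFactors = FALSE)
  }
  cluster$lesions <- rbind(cluster$lesions, les)
  gi <- cluster$truth$genes$gene == gene
  cluster$truth$genes$status[gi] <- .status_from_lesions(
    cluster$lesions[cluster$lesions$gene == gene, , drop = FALSE],
    nchar(cluster$templates[[gene]]$protein) + 1L)
  cluster
}

# Status rule shared with the scanner: no lesions -> intact; premature
# stop(s) only, with the first stop at >= 20% of the template CDS and no
# frameshift/splice/exon lesion upstream of it -> truncated; otherwise
# pseudogene.
.status_from_lesions <- function(lesions, template_codons) {
  if (nrow(lesions) == 0L) return("intact")
  stops <- lesions[lesions$kind == "premature_stop", , drop = FALSE]
  if (nrow(stops) == 0L) return("pseudogene")
  first_stop <- min(stops$codon_index)
  others <- lesions[lesions$kind != "premature_stop", , drop = FALSE]
  upstream <- others[!is.na(others$codon_index) &
                       others$codon_index <= first_stop, , drop = FALSE]
  non_codon <- others[is.na(others$codon_index), , drop = FALSE]  # splice
  if (nrow(upstream) == 0L && nrow(non_codon) == 0L &&
      (first_stop - 1L) / template_codons >= 0.2) "truncated" else "pseudogene"
}

# ---------------------------------------------------------------------------
# sister species and output

#' Derive a diverged sister-species cluster
#'
#' Rebuilds the cluster from its intact gene templates after per-site
#' substitution at `divergence` (frame-safe inside CDS, splice dinucleotides
#' preserved), with freshly drawn intergenic spacers, preserving gene order
#' and strand. Optionally implants lesions at `lesion_rate`.
#'
#' @param cluster An `edc_cluster` (typically lesion-free).
#' @param divergence Per-site substitution rate between the species.
#' @param lesion_rate Probability of one lesion per non-anchor gene.
#' @param seed Integer seed.
#' @param scaffold_id Scaffold name of the sister cluster.
#' @return An `edc_cluster`.
#' @export
sister_cluster <- function(cluster, divergence = 0.05, lesion_rate = 0,
                           seed = 1L, scaffold_id = "synthEDC_sister") {
  stopifnot(inherits(cluster, "edc_cluster"))
  with_seed(seed, {
    order_names <- cluster$truth$genes$gene
    units <- lapply(cluster$templates[order_names], .mutate_unit,
                    rate = divergence)
    strands <- cluster$truth$genes$strand
    n <- length(units)
    cfg <- cluster$config
    spacers <- vapply(seq_len(n + 1L), function(i) {
      .random_dna(50L + stats::rgeom(1L, 1 / max(cfg$intergenic_mean - 50L, 1L)))
    }, "")
    asm <- .assemble_cluster(units, strands, spacers, scaffold_id)
    sister <- structure(
      list(scaffold_id = scaffold_id, sequence = asm$sequence,
           truth = asm$truth, lesions = .empty_lesions(),
           templates = stats::setNames(units, order_names),
           genealogy = NULL, config = cfg),
      class = "edc_cluster")
    if (lesion_rate > 0) {
      targets <- sister$truth$genes$gene[sister$truth$genes$family != "anchor"]
      hit <- targets[stats::runif(length(targets)) < lesion_rate]
      for (g in hit) {
        kind <- .sample_lesion_kind(sister, g)
        sister <- implant_lesion(sister, g, kind)
      }
    }
    sister
  })
}

#' Write a synthetic cluster to disk
#'
#' Emits the scaffold FASTA, truth GFF3, a truth table TSV (gene, family,
#' architecture, status), a lesion TSV, template protein FASTA, the LCE
#' genealogy as newick (when present) and the config as JSON.
#'
#' @param cluster An `edc_cluster`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cluster <- function(cluster, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- stats::setNames(cluster$sequence, cluster$scaffold_id)
  write_fasta(seqs, file.path(dir, "scaffold.fa"))
  write_gff3(cluster$truth, file.path(dir, "truth.gff3"))
  utils::write.table(cluster$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cluster$lesions, file.path(dir, "truth_lesions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prot <- vapply(cluster$templates, `[[`, "", "protein")
  write_fasta(prot, file.path(dir, "template_proteins.faa"))
  if (!is.null(cluster$genealogy) && inherits(cluster$genealogy, "phylo")) {
    ape::write.tree(cluster$genealogy, file.path(dir, "lce_genealogy.nwk"))
  }
  cfg <- cluster$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
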