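# Nucleotide-level primitives: complementation and translation. The codon
# table is the standard genetic code as shipped by Biostrings; codons
# containing N translate to X.

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- c(Biostrings::GENETIC_CODE)
    tab
  }
})

#' Reverse complement of a DNA sequence
#'
#' @param seq Character scalar over {A,C,G,T,N}.
#' @return The Watson-Crick reverse complement; N maps to N.
#' @export
reverse_complement <- function(seq) {
  .check(is.character(seq) && length(seq) == 1L, "seq must be a single string")
  if (grepl("[^ACGTN]", seq)) {
    stop("reverse_complement is defined only over {A,C,G,T,N}", call. = FALSE)
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Translate a DNA sequence
#'
#' Translates `seq` in the given reading frame using the standard genetic
#' code, writing `*` for stop codons. On the minus strand the sequence is
#' reverse-complemented first and the frame offset applied to the
#' reverse-complemented sequence. A trailing partial codon is dropped;
#' codons containing N yield `X`.
#'
#' @param seq DNA string over {A,C,G,T,N}.
#' @param frame Frame offset 0, 1 or 2.
#' @param strand "+" or "-".
#' @return Protein string (possibly containing `*` and `X`).
#' @export
translate_dna <- function(seq, frame = 0L, strand = "+") {
  .check(frame %in% 0:2, "frame must be 0, 1 or 2")
  .check(strand %in% c("+", "-"), "strand must be '+' or '-'")
  if (strand == "-") seq <- reverse_complement(seq)
  n <- nchar(seq)
  .check(n >= frame + 3L, "sequence too short for requested frame")
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"  # codons containing N (or any non-ACGT)
  paste(aa, collapse = "")
}

# split a DNA string into complete codons (frame 0); trailing partial dropped
.codons <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return(character(0))
  substring(seq, seq.int(1L, n - 2L, 3L), seq.int(3L, n, 3L))
}

.STOPS <- c("TAA", "TAG", "TGA")
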