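# Low-complexity masking of protein queries, in the spirit of the SEG
# filter: windows whose Shannon entropy falls below a threshold are masked
# (lowercased). Masked residues are excluded from seeding but not from
# alignment extension, and the filter has an explicit off switch because
# EDC proteins have strongly biased amino-acid composition and masking them
# suppresses genuine hits.

#' Mask low-complexity protein segments
#'
#' Slides a window over the protein and computes Shannon entropy (bits,
#' log2 over residue frequencies within the window). Every residue of a
#' window with entropy below `entropy_threshold` is masked by lowercasing.
#' With `enabled = FALSE` the input is returned unchanged.
#'
#' @param protein Protein string (uppercase).
#' @param window Window length in residues (>= 4).
#' @param entropy_threshold Entropy threshold in bits.
#' @param enabled Off switch; FALSE returns the input untouched.
#' @return The protein with masked residues in lowercase.
#' @export
mask_low_complexity <- function(protein, window = 12L,
                                entropy_threshold = 2.2, enabled = TRUE) {
  if (!enabled) return(protein)
  .check(window >= 4L, "window must be >= 4 residues")
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < window) return(protein)
  masked <- logical(n)
  for (i in seq_len(n - window + 1L)) {
    f <- tabulate(factor(ch[i:(i + window - 1L)]))
    p <- f / window
    h <- -sum(p * log2(p))
    if (h < entropy_threshold) masked[i:(i + window - 1L)] <- TRUE
  }
  ch[masked] <- tolower(ch[masked])
  paste(ch, collapse = "")
}
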