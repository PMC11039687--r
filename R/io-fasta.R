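# FASTA input/output. Parsing is delegated to Biostrings; this layer
# enforces the pipeline's alphabet contract ({A,C,G,T,N} for DNA) and keeps
# record descriptions separate from ids.

#' Read a FASTA file
#'
#' Records are returned in file order, sequences uppercased. The id is the
#' header token before the first whitespace; the remainder is kept in the
#' `description` attribute.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either "DNA" (sequences must be over A,C,G,T,N after
#'   uppercasing; anything else, including IUPAC ambiguity codes, is an
#'   error because downstream codon logic is defined only over this set) or
#'   "AA" (no alphabet check beyond uppercasing).
#' @return Named character vector of sequences with a `description`
#'   character attribute of equal length. An empty file yields an empty
#'   vector with a warning.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "AA")) {
  alphabet <- match.arg(alphabet)
  .check(file.exists(path), sprintf("no such file: %s", path))
  # catch malformed headers up front with a line number: first non-blank
  # line must start with '>'
  first <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(first)))
  if (length(nonblank) == 0L) {
    warning(sprintf("empty FASTA file: %s", path))
    out <- character(0)
    attr(out, "description") <- character(0)
    return(out)
  }
  if (!startsWith(trimws(first[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA header at line %d of %s", nonblank[1], path),
         call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  names(seqs) <- ids
  if (alphabet == "DNA") {
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop(sprintf(
        "sequence '%s' contains characters outside {A,C,G,T,N}; ambiguity codes are not supported",
        ids[which(bad)[1]]), call. = FALSE)
    }
  }
  attr(seqs, "description") <- desc
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences; an optional
#'   `description` attribute is appended to headers after a space.
#' @param path Output path.
#' @param width Line-wrap width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  .check(!is.null(names(seqs)) && all(nzchar(names(seqs))),
         "write_fasta requires named sequences")
  desc <- attr(seqs, "description")
  headers <- names(seqs)
  if (!is.null(desc)) {
    headers <- ifelse(nzchar(desc), paste(headers, desc), headers)
  }
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}
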