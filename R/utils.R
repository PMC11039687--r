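# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds R's RNG, runs `expr`, and restores the caller's RNG state, so that
#' generator functions are deterministic given their `seed` argument without
#' disturbing the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stopifnot() with a readable message
.check <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Genomic interval constructor
#'
#' Intervals are 0-based half-open `[start, end)` on a named scaffold strand.
#' This is the single internal coordinate convention; GFF3 emission and
#' report tables convert to 1-based closed.
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand "+" or "-".
#' @return A one-row data frame with columns start, end, strand.
#' @export
interval <- function(start, end, strand = "+") {
  .check(all(start >= 0) && all(start < end), "interval requires 0 <= start < end")
  .check(all(strand %in% c("+", "-")), "strand must be '+' or '-'")
  data.frame(start = as.integer(start), end = as.integer(end), strand = strand)
}

# length of a 0-based half-open interval
.iv_len <- function(start, end) as.integer(end - start)

# 1-based closed rendering for reports
.iv_1based <- function(start, end) sprintf("%d-%d", start + 1L, end)
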