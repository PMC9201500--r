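#' Significance codes for p-values
#'
#' Maps p-values to the conventional star codes used in the output tables:
#' `***` (p < 0.001), `**` (p < 0.01), `*` (p < 0.05), `ns` otherwise.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Character vector of codes.
#' @export
signif_code <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
             ifelse(p[ok] < 0.01,  "**",
             ifelse(p[ok] < 0.05,  "*", "ns")))
  out
}

# internal: stop with a consistent prefix
abort_input <- function(...) stop(..., call. = FALSE)

# internal: recycle a scalar to length n or check length
recycle_to <- function(x, n, what) {
  if (length(x) == 1L) return(rep(x, n))
  if (length(x) != n) {
    abort_input(sprintf("'%s' must have length 1 or %d, got %d", what, n, length(x)))
  }
  x
}

# internal: check a single positive number
check_pos <- function(x, what, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (strict && x <= 0) || (!strict && x < 0)) {
    abort_input(sprintf("'%s' must be a single %s number", what,
                        if (strict) "positive" else "nonnegative"))
  }
  invisible(x)
}
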