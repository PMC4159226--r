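# internal helpers shared across modules

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; catalogue percentages are
#' reported with halves rounded away from zero (so 26/28 -> 93, 22/28 -> 79).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-interval membership
in_interval <- function(x, lo, hi) is.finite(x) & x >= lo & x <= hi

# do [a1,a2] and [b1,b2] intersect? (closed intervals)
spans_intersect <- function(a1, a2, b1, b2) {
  a1 <= b2 & b1 <= a2
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
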