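#' Round half-up
#'
#' Rounds to `digits` decimal places with halves away from zero, the
#' convention used for the printed percentages in study reports (base R's
#' `round()` rounds half to even, which turns 86.25 into 86.2).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return rounded numeric vector.
#' @export
percent_round <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector of log-scale values.
#' @return scalar log-sum-exp.
#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
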