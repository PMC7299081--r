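#' Nearest-rank percentile
#'
#' The p-th percentile by the nearest-rank definition: the smallest value
#' whose rank is at least `ceiling(p/100 * n)` in the sorted sample.
#'
#' @param x Numeric vector.
#' @param p Percentile in (0, 100].
#' @return A single value of `x`.
#' @export
percentile_nearest_rank <- function(x, p) {
  stopifnot(length(x) > 0, p > 0, p <= 100)
  sort(x)[ceiling(p / 100 * length(x))]
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
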