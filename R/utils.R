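#' Round half away from zero
#'
#' Base R's `round()` rounds half to even ("banker's rounding"); reported
#' percentages in this package follow the more common half-up convention, so
#' that e.g. 84/445 compounds prints as 18.88%.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(100 * 84 / 445, 2) # 18.88
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count, rounded half-up to two decimals
#'
#' @param count numerator count(s).
#' @param total denominator count.
#' @return numeric percentage(s) on the 0-100 scale, two decimals.
#' @examples
#' percent_of(48, 167) # 28.74
#' @export
percent_of <- function(count, total) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, 2)
}

# stop with a classed condition; all validation errors share the
# "netpharm_error" class so callers can catch them uniformly
np_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "netpharm_error"), ...)
}

# derive an independent substream seed from a master seed; kept below 2^31
substream_seed <- function(seed, k) {
  (as.numeric(seed) + 1000003 * k) %% 2147483629
}
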