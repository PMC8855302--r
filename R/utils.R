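#' Round half away from zero
#'
#' Decimal rounding with the "half-up" tie rule used when printing overlap
#' percentages (base \code{round()} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(85.65, 1)  # 85.7, not 85.6
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by one ulp so values that are exactly .5 in decimal but stored a
  # hair below it in binary still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# geometric mean of strictly positive values, NA-aware
geomean <- function(x, na.rm = TRUE) {
  exp(mean(log(x), na.rm = na.rm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
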