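#' Round half away from zero
#'
#' Fixed-precision rounding that resolves ties upward in absolute value
#' (2.5 -> 3), matching how niche-width tables are conventionally printed,
#' rather than base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

## population (n) or sample (n - 1) variance of a vector
variance_by <- function(x, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  n <- length(x)
  if (n < 2) return(NA_real_)
  v <- stats::var(x)               # n - 1 denominator
  if (convention == "population") v * (n - 1) / n else v
}

check_convention <- function(convention) {
  match.arg(convention, c("population", "sample"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
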