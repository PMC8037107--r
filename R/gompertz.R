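#' Generate a synthetic Gompertz life table
#'
#' Builds a deterministic annual life table from a Gompertz mortality
#' hazard: the one-year death probability at age `x` is
#' `qx = 1 - exp(-a * exp(b * x))`, clamped at 1 and rounded to six
#' decimals. With `b = 0` this reduces to the constant-hazard
#' (exponential) table `qx = 1 - exp(-a)`.
#'
#' The defaults (`a = 6.3e-5`, `b = 0.085`) are calibrated so remaining
#' life expectancy at age 73 is roughly 13 years, the ballpark of the 2014
#' US all-sex period life table; they are a documented stand-in, not a fit
#' to vital statistics.
#'
#' @param a Baseline hazard per year, > 0.
#' @param b Log-hazard slope per year, >= 0.
#' @param ages Integer ages to tabulate (default 0 through 100).
#' @return A `cea_lifetable`.
#' @export
#' @examples
#' lt <- generate_lifetable()
#' qx_at(lt, c(60, 73, 85))
generate_lifetable <- function(a = 6.3e-5, b = 0.085, ages = 0:100) {
  if (!is.finite(a) || a <= 0) rlang::abort("`a` must be positive.")
  if (!is.finite(b) || b < 0) rlang::abort("`b` must be non-negative.")
  qx <- round(pmin(1, 1 - exp(-a * exp(b * ages))), 6)
  new_lifetable(tibble::tibble(age = as.integer(ages), qx = qx))
}
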