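#' Library of temporal mean-trajectory patterns
#'
#' Eight named cubic polynomials on the time grid `t = 1..m` that span the
#' qualitative shapes seen in short time-course expression data: flat,
#' monotone increase/decrease, a single peak, a single dip, S-shaped curves
#' with two fluctuations, and a saturating rise. Each pattern is stored as
#' its coefficient 4-vector `(b0, b1, b2, b3)` so that the trajectory is
#' `g(t) = b0 + b1*t + b2*t^2 + b3*t^3`.
#'
#' @return A named list of numeric length-4 coefficient vectors.
#' @examples
#' lib <- pattern_library()
#' eval_pattern(lib$peak, 1:6)
#' @export
pattern_library <- function() {
  list(
    flat           = c(1.0, 0, 0, 0),
    increase       = c(0.0, 0.4, 0, 0),
    decrease       = c(2.4, -0.4, 0, 0),
    peak           = c(-1.92, 2.24, -0.32, 0),
    dip            = c(3.92, -2.24, 0.32, 0),
    rise_fall_rise = c(-2.0, 4.6, -1.8, 0.2),
    fall_rise_fall = c(4.0, -4.6, 1.8, -0.2),
    saturating     = c(0.0, 1.0, -0.1, 0)
  )
}

#' Evaluate a polynomial pattern on a time grid
#'
#' @param coef Numeric coefficient vector `(b0, ..., bK)`, lowest degree first.
#' @param times Numeric vector of timepoints.
#' @return Numeric vector of `g(times)`.
#' @export
eval_pattern <- function(coef, times) {
  stopifnot(is.numeric(coef), length(coef) >= 1, is.numeric(times))
  drop(outer(times, seq_along(coef) - 1, "^") %*% coef)
}
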