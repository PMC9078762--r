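# Minimum-risk estimators for the negative exponential distribution (NED)
# with scale theta (mean theta): shrinkage of the sample mean abar for theta,
# and of abar^2 for theta^2.
#
# abar of an NED(theta) sample of size n is Gamma(n, scale theta/n)
# (equivalently 2 n abar / theta ~ chi-square with 2n df), so
# E exp(s abar) = (1 - s theta/n)^{-n} and all moments are products
# (n+1)...(n+2k-1)/n^(2k-1).  The exact invariant LINEX risk of z*abar is
# available in closed form; for z5*abar^2 the exact risk is infinite
# whenever a*z5 > 0 (the MGF of a squared gamma diverges), which is why the
# theta^2 problem is treated through the cubic-truncated risk only.

#' MSE-optimal shrinkage of the NED sample mean
#'
#' `E1 = n*abar/(n+1)` has relative MSE `1/(n+1)`, strictly below the `1/n`
#' of the unshrunk mean.
#'
#' @param n sample size.
#' @return List with `s = n/(n+1)` and `relative_mse = 1/(n+1)`.
#' @export
shrink_scale_mse <- function(n) {
  check_count(n)
  list(s = n / (n + 1), relative_mse = 1 / (n + 1))
}

#' Exact invariant LINEX risk of a shrunk NED scale estimator
#'
#' Risk of `z * abar` for `theta`:
#' `b * (exp(-a) (1 - a z/n)^{-n} - a z + a - 1)`, finite for `a z < n`.
#'
#' @param z shrinkage coefficient (vectorized).
#' @param n sample size.
#' @param a,b LINEX shape and scale.
#' @return Risk values.
#' @export
invariant_risk_scale <- function(z, n, a, b = 1) {
  check_linex(a, b); check_count(n)
  if (any(a * z >= n))
    stop(sprintf("MGF diverges: need a*z < n = %d", n), call. = FALSE)
  g <- -a - n * log1p(-a * z / n)
  b * (expm1(g) - a * (z - 1))
}

# derivative in z (internal): b*a*(exp(-a)(1 - a z/n)^{-(n+1)} - 1)
invariant_risk_scale_deriv <- function(z, n, a, b = 1) {
  b * a * (exp(-a) * (1 - a * z / n)^(-(n + 1)) - 1)
}

#' LINEX-optimal shrinkage of the NED scale estimator
#'
#' Exact stationary point of the invariant LINEX risk of `z * abar`:
#' `z_min = (n/a) (1 - exp(-a/(n+1)))`.  Tends to `n/(n+1)` as `a -> 0`
#' and lies in `(0, 1)` for `a > 0`.
#'
#' @param n sample size.
#' @param a LINEX shape (nonzero).
#' @return The coefficient `z_min`.
#' @export
#' @examples
#' optimal_shrink_scale_linex(10, 0.5)   # 20*(1 - exp(-1/22))
optimal_shrink_scale_linex <- function(n, a) {
  check_linex(a, 1); check_count(n)
  -(n / a) * expm1(-a / (n + 1))
}

# exact normalized even moments of abar for NED: E abar^(2k) / theta^(2k)
ned_abar_moments <- function(n) {
  list(m2 = (n + 1) / n,
       m4 = (n + 1) * (n + 2) * (n + 3) / n^3,
       m6 = (n + 1) * (n + 2) * (n + 3) * (n + 4) * (n + 5) / n^5)
}

#' Cubic-truncated invariant LINEX risk of a shrunk NED theta^2 estimator
#'
#' Third-order truncated risk of `z5 * abar^2` as an estimator of `theta^2`,
#' built from the exact gamma moments of `abar` up to the sixth (factors
#' `(n+1)...(n+5)/n^5`).  The *exact* risk is infinite for `a z5 > 0`
#' because the MGF of a squared gamma variable diverges, so the truncation
#' is the object of study, and the result carries attribute
#' `truncated = TRUE` as a flag.
#'
#' @param z5 shrinkage coefficient; the meaningful range is `[0, 1]` and a
#'   warning is given outside it (the formula itself remains defined).
#' @param n sample size.
#' @param a,b LINEX shape and scale.
#' @return Truncated risk values with attribute `truncated = TRUE`.
#' @export
truncated_risk_scale2 <- function(z5, n, a, b = 1) {
  check_linex(a, b); check_count(n)
  if (any(z5 < 0 | z5 > 1))
    warning("'z5' outside [0, 1]; truncated risk evaluated anyway")
  m <- ned_abar_moments(n)
  ed2 <- z5^2 * m$m4 - 2 * z5 * m$m2 + 1
  ed3 <- z5^3 * m$m6 - 3 * z5^2 * m$m4 + 3 * z5 * m$m2 - 1
  structure(b * (a^2 / 2 * ed2 + a^3 / 6 * ed3), truncated = TRUE)
}

#' LINEX-optimal shrinkage for the NED theta^2 estimator (truncated risk)
#'
#' Minimizes the cubic-truncated risk of `z5 * abar^2`.  The stationarity
#' condition is the quadratic `a m6 z5^2 + 2(1-a) m4 z5 + (a-2) m2 = 0` in
#' the exact gamma moments; the root is selected inside the bracket
#' `[(a-1) n^2 / (a (n+5)(n+4)), 1]` (the second-order condition), and if
#' both roots qualify the one with smaller truncated risk is taken.  As
#' `a -> 0` the optimum tends to the MSE-optimal
#' `m2/m4 = n^2/((n+2)(n+3))`.
#'
#' @param n sample size.
#' @param a,b LINEX shape and scale.
#' @return List with `z5_min` and the selection `bracket` (length-2 vector).
#' @export
optimal_shrink_scale2_linex <- function(n, a, b = 1) {
  check_linex(a, b); check_count(n)
  m <- ned_abar_moments(n)
  lower <- (a - 1) * n^2 / (a * (n + 5) * (n + 4))
  bracket <- c(lower, 1)
  z5 <- solve_shrink_quadratic(
    A = a * m$m6, B = 2 * (1 - a) * m$m4, C = (a - 2) * m$m2,
    objective = function(z) as.numeric(suppressWarnings(truncated_risk_scale2(z, n, a, b))),
    interval = bracket)
  list(z5_min = z5, bracket = bracket)
}
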