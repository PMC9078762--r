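# Shrinkage estimators for a normal mean mu, for mu^2 and for sigma^2, with
# the coefficient of variation v = sigma/mu assumed known (mu > 0).
#
# Estimators are of the form z * abar (for mu) and t * abar^2 (for mu^2); the
# coefficient is chosen to minimize either mean squared error or the
# invariant-form LINEX risk.  Exact risks come from the moment generating
# functions: abar is normal, so E exp(s*abar) is closed-form, and abar^2 is a
# scaled noncentral chi-square.  The cubic Taylor truncation of the risk
# (e^u - u - 1 ~ u^2/2 + u^3/6) gives the closed-form approximate optima,
# which are always validated against the exact numeric minimizer.

#' MSE-optimal shrinkage of the sample mean (known coefficient of variation)
#'
#' Among estimators `s * abar` of a normal mean, MSE is minimized by
#' `s = n/(n + v^2)`, with relative MSE `MSE/sigma^2 = (1/n)/(1 + v^2/n)`,
#' strictly below the `1/n` of the unshrunk mean.
#'
#' @param n sample size.
#' @param v known coefficient of variation `sigma/mu > 0`.
#' @return List with components `s` (shrinkage coefficient) and
#'   `relative_mse` (`MSE(s*abar)/sigma^2`).
#' @export
#' @examples
#' optimal_shrink_mean_mse(4, 1)   # s = 0.8
optimal_shrink_mean_mse <- function(n, v) {
  check_count(n); check_pos(v, "v")
  s <- n / (n + v^2)
  list(s = s, relative_mse = (1 / n) / (1 + v^2 / n))
}

#' Exact invariant LINEX risk of a shrunk normal mean
#'
#' Risk of `z * abar` as an estimator of `mu` under invariant LINEX loss,
#' computed from the normal MGF of `abar`:
#' `b * (exp(a(z-1) + a^2 z^2 v^2/(2n)) - a(z-1) - 1)`.
#'
#' @param z shrinkage coefficient (vectorized).
#' @param n sample size.
#' @param v known coefficient of variation.
#' @param a,b LINEX shape and scale.
#' @return Risk values (same length as `z`).
#' @export
invariant_risk_mean <- function(z, n, v, a, b = 1) {
  check_linex(a, b); check_count(n); check_pos(v, "v")
  g <- a * (z - 1) + a^2 * z^2 * v^2 / (2 * n)
  # expm1 keeps the O(a^2) risk accurate as a -> 0
  b * (expm1(g) - a * (z - 1))
}

# derivative of invariant_risk_mean in z (internal)
invariant_risk_mean_deriv <- function(z, n, v, a, b = 1) {
  g <- a * (z - 1) + a^2 * z^2 * v^2 / (2 * n)
  b * ((a + a^2 * z * v^2 / n) * exp(g) - a)
}

# cubic-truncated invariant LINEX risk of z*abar (internal; used for root
# selection and for documenting the truncation the closed form comes from)
truncated_risk_mean <- function(z, n, v, a, b = 1) {
  u <- v^2 / n
  ey2 <- (z - 1)^2 + z^2 * u
  ey3 <- (z - 1)^3 + 3 * (z - 1) * z^2 * u
  b * (a^2 / 2 * ey2 + a^3 / 6 * ey3)
}

#' LINEX-optimal shrinkage of the sample mean
#'
#' Minimizes the invariant LINEX risk of `z * abar` over `z`.  Returns both
#' the exact numeric minimizer (root of the exact risk derivative, found by
#' bisection to high precision) and the closed-form approximation obtained
#' from the cubic-truncated risk, whose stationarity condition is the
#' quadratic `a(1+3u) z^2 + 2(1+u)(1-a) z + (a-2) = 0` with `u = v^2/n`.
#' As `a -> 0` both tend to the MSE-optimal `n/(n + v^2)`.
#'
#' @inheritParams invariant_risk_mean
#' @return List with `z_min` (exact numeric optimum) and `z_approx`
#'   (truncated-risk closed form).
#' @export
optimal_shrink_mean_linex <- function(n, v, a, b = 1) {
  check_linex(a, b); check_count(n); check_pos(v, "v")
  dfun <- function(z) invariant_risk_mean_deriv(z, n, v, a, b)
  hi <- 2
  while (dfun(hi) < 0 && hi < 1e6) hi <- hi * 2
  z_min <- stats::uniroot(dfun, c(1e-10, hi), tol = 1e-12)$root
  u <- v^2 / n
  z_approx <- solve_shrink_quadratic(
    A = a * (1 + 3 * u), B = 2 * (1 + u) * (1 - a), C = a - 2,
    objective = function(z) truncated_risk_mean(z, n, v, a, b),
    interval = c(0, 2))
  list(z_min = z_min, z_approx = z_approx)
}

#' Minimum-variance unbiased estimator of the squared normal mean
#'
#' `abar^2 - d2/n`, where `d2` is the unbiased sample variance.  Unbiased for
#' `mu^2` but may be negative in small samples, which motivates the shrinkage
#' alternatives.
#'
#' @param xbar sample mean.
#' @param d2 unbiased sample variance (divisor `n - 1`).
#' @param n sample size (`>= 2`).
#' @return The estimate (possibly negative).
#' @export
mvue_mu2 <- function(xbar, d2, n) {
  check_count(n, least = 2L)
  if (any(d2 < 0)) stop("'d2' must be nonnegative", call. = FALSE)
  xbar^2 - d2 / n
}

# exact normalized moments of abar: E[abar^(2k)] / mu^(2k), u = v^2/n
normal_abar_moments <- function(n, v) {
  u <- v^2 / n
  list(u = u,
       m2 = 1 + u,
       m4 = 1 + 6 * u + 3 * u^2,
       m6 = 1 + 15 * u + 45 * u^2 + 15 * u^3)
}

#' MSE-optimal shrinkage for the squared normal mean
#'
#' The MSE of `t * abar^2` as an estimator of `mu^2` is minimized at
#' `t2 = mu^2 E[abar^2] / E[abar^4] = (1 + u)/(1 + 6u + 3u^2)` with
#' `u = v^2/n`, computed from the exact normal moments.
#'
#' @inheritParams optimal_shrink_mean_mse
#' @return The coefficient `t2` in `(0, 1)`.
#' @export
#' @examples
#' optimal_shrink_mu2_mse(10, 1)   # 1.1/1.63
optimal_shrink_mu2_mse <- function(n, v) {
  check_count(n); check_pos(v, "v")
  m <- normal_abar_moments(n, v)
  m$m2 / m$m4
}

#' Invariant LINEX risk of a shrunk estimator of the squared normal mean
#'
#' Risk of `t * abar^2` for `mu^2` under invariant LINEX loss.  The exact
#' risk uses the noncentral chi-square MGF of `abar^2`,
#' `E exp(s abar^2) = (1 - 2 s sigma^2/n)^{-1/2} exp(s mu^2/(1 - 2 s sigma^2/n))`,
#' finite only for `a t < n/(2 v^2)` (in normalized form); outside that
#' domain an error is signalled.  `truncated = TRUE` evaluates instead the
#' cubic Taylor truncation used for the closed-form optimum.
#'
#' @param t shrinkage coefficient (vectorized).
#' @inheritParams invariant_risk_mean
#' @param truncated if `TRUE`, return the cubic-truncated risk variant.
#' @return Risk values.
#' @export
invariant_risk_mu2 <- function(t, n, v, a, b = 1, truncated = FALSE) {
  check_linex(a, b); check_count(n); check_pos(v, "v")
  m <- normal_abar_moments(n, v)
  if (truncated) {
    ed2 <- t^2 * m$m4 - 2 * t * m$m2 + 1
    ed3 <- t^3 * m$m6 - 3 * t^2 * m$m4 + 3 * t * m$m2 - 1
    return(b * (a^2 / 2 * ed2 + a^3 / 6 * ed3))
  }
  w <- 2 * a * t * v^2 / n
  if (any(w >= 1))
    stop(sprintf("MGF diverges: need a*t < n/(2 v^2) = %g", n / (2 * v^2)),
         call. = FALSE)
  g <- a * (t / (1 - w) - 1) - log1p(-w) / 2
  e_d <- t * m$m2 - 1
  b * (expm1(g) - a * e_d)
}

#' LINEX-optimal shrinkage for the squared normal mean
#'
#' `t4_min` is the numeric minimizer of the exact invariant LINEX risk of
#' `t * abar^2`; `t4_approx` is the root of the cubic-truncated stationarity
#' condition `a m6 t^2 + 2 m4 (1-a) t + (a-2) m2 = 0` built from the exact
#' normal moments `m2, m4, m6` of `abar`.  Both tend to the MSE-optimal
#' [optimal_shrink_mu2_mse()] as `a -> 0`.
#'
#' @inheritParams invariant_risk_mean
#' @return List with `t4_min` and `t4_approx`.
#' @export
optimal_shrink_mu2_linex <- function(n, v, a, b = 1) {
  check_linex(a, b); check_count(n); check_pos(v, "v")
  ub <- if (a > 0) min(2, (1 - 1e-9) * n / (2 * a * v^2)) else 2
  t4_min <- stats::optimize(function(t) invariant_risk_mu2(t, n, v, a, b),
                            c(1e-10, ub), tol = 1e-10)$minimum
  m <- normal_abar_moments(n, v)
  t4_approx <- solve_shrink_quadratic(
    A = a * m$m6, B = 2 * m$m4 * (1 - a), C = (a - 2) * m$m2,
    objective = function(t) invariant_risk_mu2(t, n, v, a, b, truncated = TRUE),
    interval = c(0, 2))
  list(t4_min = t4_min, t4_approx = t4_approx)
}

#' Relative MSE of divisor-d estimators of the normal variance
#'
#' For the estimator `sum((x - abar)^2) / d` of `sigma^2`,
#' `MSE/sigma^4 = 2(n-1)/d^2 + ((n-1)/d - 1)^2`.  The unbiased divisor
#' `d = n - 1` gives `2/(n-1)`; the MSE-optimal divisor is `d = n + 1` with
#' value `2/(n+1)`.
#'
#' @param n sample size (`>= 2`).
#' @param d positive divisor.
#' @return `MSE/sigma^4`.
#' @export
sigma2_divisor_mse <- function(n, d) {
  check_count(n, least = 2L)
  if (any(d <= 0)) stop("'d' must be positive", call. = FALSE)
  2 * (n - 1) / d^2 + ((n - 1) / d - 1)^2
}
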