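# Shared internal helpers.

# Stable selection of a root of A z^2 + B z + C = 0 for the cubic-truncated
# LINEX risk stationarity conditions.  All three shrinkage problems (normal
# mean, normal mu^2, NED theta^2) reduce to this with A -> 0 as the LINEX
# shape a -> 0, so the quadratic formula is evaluated in the cancellation-free
# form and the A = 0 (squared-error) limit -C/B is taken explicitly.
# `objective` breaks ties when several roots fall inside `interval`.
solve_shrink_quadratic <- function(A, B, C, objective, interval) {
  if (abs(A) < 1e-12 * max(abs(B), 1)) {
    root <- -C / B
    return(root)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0)
    stop("truncated-risk stationarity condition has no real root", call. = FALSE)
  sgn <- if (B >= 0) 1 else -1
  q <- -(B + sgn * sqrt(disc)) / 2
  roots <- unique(c(q / A, if (q != 0) C / q))
  cand <- roots[roots >= interval[1] & roots <= interval[2]]
  if (length(cand) == 0L)
    stop(sprintf("no stationarity root in [%g, %g] (roots: %s)",
                 interval[1], interval[2],
                 paste(signif(roots, 6), collapse = ", ")), call. = FALSE)
  if (length(cand) > 1L) cand <- cand[which.min(vapply(cand, objective, 0))]
  cand
}

check_count <- function(n, least = 1L, what = "n") {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < least ||
      n != round(n))
    stop(sprintf("'%s' must be an integer >= %d", what, least), call. = FALSE)
  invisible(TRUE)
}

check_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", what), call. = FALSE)
  invisible(TRUE)
}

#' Convert a gamma scale parameter to a rate (and back)
#'
#' The gamma hyperparameter written beta enters the censored-exponential
#' posterior as a *rate* (it adds to the total time at risk) but the Poisson
#' intensity prior as a *scale* (prior mean `alpha*beta`).  This one-line
#' converter makes the switch explicit when moving between the two
#' parameterizations.
#'
#' @param x positive scale (or rate) value.
#' @return `1/x`.
#' @export
scale_to_rate <- function(x) {
  check_pos(x, "x")
  1 / x
}
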