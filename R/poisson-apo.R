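# Sequential Bayes estimation of a homogeneous Poisson intensity under LINEX
# loss with linear sampling cost, and the asymptotically pointwise optimal
# (APO) stopping rule.
#
# The prior is Gamma(shape alpha, SCALE beta) -- prior mean alpha*beta; this
# module deliberately uses the scale convention (the censored-exponential
# module uses the rate convention; see scale_to_rate()).  After observing the
# process to time t with R(t) events the posterior is Gamma(alpha + R(t),
# rate t + 1/beta).  The posterior LINEX risk of the Bayes estimate is
#   U_t = (alpha + R(t)) * (s - log(1 + s)),   s = a*beta/(t*beta + 1),
# which decreases continuously between events and jumps up at events.  The
# APO rule stops at tau = inf{t >= 0 : U_t <= cost * t}; for small cost,
# t*U_t -> a^2*theta/2 so tau ~ a*sqrt(theta/(2*cost)).

#' Poisson process path
#'
#' Ordered event times of a point process observed on `[0, horizon]`.
#'
#' @param event_times strictly increasing nonnegative event times, all
#'   `<= horizon`.
#' @param horizon positive observation limit.
#' @return An object of class `"poisson_path"`.
#' @export
poisson_path <- function(event_times, horizon) {
  check_pos(horizon, "horizon")
  event_times <- as.numeric(event_times)
  if (anyNA(event_times)) stop("missing event times", call. = FALSE)
  if (length(event_times)) {
    if (any(event_times < 0) || any(event_times > horizon))
      stop("event times must lie in [0, horizon]", call. = FALSE)
    if (is.unsorted(event_times, strictly = TRUE))
      stop("event times must be strictly increasing", call. = FALSE)
  }
  structure(list(event_times = event_times, horizon = horizon),
            class = "poisson_path")
}

#' @export
print.poisson_path <- function(x, ...) {
  cat(sprintf("Poisson process path: %d events on [0, %g]\n",
              length(x$event_times), x$horizon))
  invisible(x)
}

#' Simulate a homogeneous Poisson process path
#'
#' @param theta positive intensity.
#' @param horizon positive observation limit.
#' @param seed optional integer seed (the RNG is untouched if `NULL`).
#' @return A [poisson_path()].
#' @export
simulate_poisson_path <- function(theta, horizon, seed = NULL) {
  check_pos(theta, "theta"); check_pos(horizon, "horizon")
  if (!is.null(seed)) set.seed(seed)
  # cumulative exponential gaps (strictly increasing by construction)
  block <- max(16L, ceiling(theta * horizon + 6 * sqrt(theta * horizon)))
  times <- cumsum(stats::rexp(block, theta))
  while (times[length(times)] < horizon) {
    times <- c(times, times[length(times)] + cumsum(stats::rexp(block, theta)))
  }
  poisson_path(times[times <= horizon], horizon)
}

#' Number of events observed by time t
#'
#' @param path a [poisson_path()].
#' @param t observation time(s), in `[0, horizon]` (vectorized).
#' @return Integer count(s) `R(t)`.
#' @export
n_events <- function(path, t) {
  stopifnot(inherits(path, "poisson_path"))
  if (any(t < 0 | t > path$horizon))
    stop("'t' must lie in [0, horizon]", call. = FALSE)
  findInterval(t, path$event_times)
}

#' Posterior for the Poisson intensity at time t
#'
#' Conjugate update of the Gamma(shape, scale) prior after observing the
#' path up to `t`: shape `prior_shape + R(t)`, rate `t + 1/prior_scale`.
#'
#' @inheritParams n_events
#' @param prior_shape,prior_scale gamma prior, *scale* convention (prior
#'   mean `prior_shape * prior_scale`).
#' @return A [gamma_dist()] (rate convention).
#' @export
poisson_posterior <- function(prior_shape, prior_scale, path, t) {
  check_pos(prior_shape, "prior_shape"); check_pos(prior_scale, "prior_scale")
  gamma_dist(prior_shape + n_events(path, t), t + 1 / prior_scale)
}

#' Sequential Bayes estimate of the Poisson intensity under LINEX loss
#'
#' `((alpha + R(t))/a) * log(1 + a*beta/(t*beta + 1))`, the Bayes estimator
#' from the current posterior; tends to the posterior mean as `a -> 0`.
#'
#' @inheritParams poisson_posterior
#' @param a LINEX shape; needs `a*beta/(t*beta + 1) > -1`.
#' @return The Bayes estimate.
#' @export
theta_tilde <- function(prior_shape, prior_scale, path, t, a) {
  post <- poisson_posterior(prior_shape, prior_scale, path, t)
  bayes_estimate_gamma(post$shape, post$rate, a)
}

#' Posterior LINEX risk U_t of the sequential Bayes estimate
#'
#' `U_t = b*(alpha + R(t)) * (s - log(1 + s))` with
#' `s = a*beta/(t*beta + 1)`; identical to applying
#' [posterior_linex_risk_gamma()] to the current posterior.  Decreases
#' continuously in `t` between events and jumps up at event times.
#'
#' @inheritParams theta_tilde
#' @param b LINEX scale.
#' @return Nonnegative risk value.
#' @export
posterior_risk_u <- function(prior_shape, prior_scale, path, t, a, b = 1) {
  post <- poisson_posterior(prior_shape, prior_scale, path, t)
  posterior_linex_risk_gamma(post$shape, post$rate, a, b)
}

#' Time-scaled posterior risk C_t = t * U_t
#'
#' For a long path with true intensity `theta`, `C_t -> b * a^2 * theta / 2`,
#' the Taylor asymptote that drives the APO stopping-time approximation.
#'
#' @inheritParams posterior_risk_u
#' @return `t * U_t`.
#' @export
scaled_risk_c <- function(prior_shape, prior_scale, path, t, a, b = 1) {
  t * posterior_risk_u(prior_shape, prior_scale, path, t, a, b)
}

# U_t for a fixed event count r (internal, avoids repeated path lookups)
u_given_r <- function(r, t, alpha, beta, a, b) {
  s <- a * beta / (t * beta + 1)
  b * (alpha + r) * (s - log1p(s))
}

#' APO stopping rule for the Poisson intensity
#'
#' Stops at `tau = inf{t >= 0 : U_t <= cost * t}`.  Between events `U_t` is
#' continuous and decreasing while `cost*t` increases, so each inter-event
#' interval holds at most one crossing; the rule scans intervals in order
#' and locates the crossing by bisection (absolute tolerance `1e-10` on the
#' root, refined until `|U_tau - cost*tau| <= 1e-12` where possible).  At an
#' event time the posterior is taken right-continuously (the event counts).
#'
#' @inheritParams posterior_risk_u
#' @param path a [poisson_path()]; if no crossing occurs before the horizon
#'   the decision is returned with `truncated = TRUE` and the state at the
#'   horizon.
#' @param cost positive sampling cost per unit time.
#' @return An object of class `"apo_decision"`: list with `tau`, `r_at_tau`,
#'   `theta_tilde`, `posterior_risk` (`U_tau`), `sampling_cost`
#'   (`cost*tau`), `truncated`, plus the configuration.
#' @export
apo_stop <- function(path, prior_shape, prior_scale, a, b = 1, cost) {
  stopifnot(inherits(path, "poisson_path"))
  check_pos(prior_shape, "prior_shape"); check_pos(prior_scale, "prior_scale")
  check_linex(a, b); check_pos(cost, "cost")
  if (a < 0 && !(prior_shape > 1 && prior_scale < -1 / a))
    warning("for a < 0 the asymptotic theory assumes shape > 1 and ",
            "0 < scale < -1/a")
  ev <- path$event_times
  bounds <- c(0, ev, path$horizon)
  g <- function(t, r) u_given_r(r, t, prior_shape, prior_scale, a, b) - cost * t
  tau <- NA_real_; r_tau <- NA_integer_
  for (i in seq_len(length(bounds) - 1L)) {
    t_lo <- bounds[i]; t_hi <- bounds[i + 1L]
    r <- i - 1L  # events counted on [t_lo, t_hi)
    if (g(t_lo, r) <= 0) { tau <- t_lo; r_tau <- r; break }
    if (t_hi > t_lo && g(t_hi, r) <= 0) {
      # g is continuous and strictly decreasing on the interval: bisect.
      lo <- t_lo; hi <- t_hi
      for (k in 1:100) {
        if (hi - lo < 2e-16 * max(1, hi)) break
        mid <- (lo + hi) / 2
        if (g(mid, r) > 0) lo <- mid else hi <- mid
      }
      tau <- hi
      r_tau <- r
      break
    }
  }
  truncated <- is.na(tau)
  if (truncated) { tau <- path$horizon; r_tau <- length(ev) }
  structure(list(
    tau = tau, r_at_tau = as.integer(r_tau),
    theta_tilde = theta_tilde(prior_shape, prior_scale, path, tau, a),
    posterior_risk = u_given_r(r_tau, tau, prior_shape, prior_scale, a, b),
    sampling_cost = cost * tau, truncated = truncated,
    cost = cost, prior_shape = prior_shape, prior_scale = prior_scale,
    a = a, b = b), class = "apo_decision")
}

#' @export
print.apo_decision <- function(x, digits = 5, ...) {
  cat("APO stopping decision",
      if (x$truncated) " (TRUNCATED at horizon: no crossing)" else "", "\n",
      sep = "")
  cat(sprintf("  tau = %s with R(tau) = %d events\n",
              format(x$tau, digits = digits), x$r_at_tau))
  cat(sprintf("  intensity estimate theta~ = %s\n",
              format(x$theta_tilde, digits = digits)))
  cat(sprintf("  posterior risk U = %s, sampling cost c*tau = %s\n",
              format(x$posterior_risk, digits = digits),
              format(x$sampling_cost, digits = digits)))
  invisible(x)
}

#' Monte-Carlo Bayes risk of the APO sequential procedure
#'
#' Draws `theta` from the Gamma(shape, scale) prior, simulates the process,
#' applies [apo_stop()], and averages the total risk
#' `U_tau + cost * tau`.  Warns when more than 1% of the replicates hit the
#' horizon without stopping.
#'
#' @inheritParams apo_stop
#' @param cost positive sampling cost per unit time.
#' @param reps number of replicates (`>= 100`).
#' @param seed integer seed.
#' @param horizon observation limit for each simulated path.
#' @return List with `risk` (mean total risk), `mean_tau`, `se` (standard
#'   error of the risk), `n_truncated`.
#' @export
sequential_bayes_risk <- function(prior_shape, prior_scale, a, b = 1, cost,
                                  reps, seed, horizon) {
  check_count(reps, least = 100L, what = "reps")
  set.seed(seed)
  sub <- sample.int(2147483646L, reps)
  total <- tau <- numeric(reps); trunc_n <- 0L
  for (i in seq_len(reps)) {
    set.seed(sub[i])
    theta <- stats::rgamma(1, shape = prior_shape, scale = prior_scale)
    path <- simulate_poisson_path(theta, horizon)
    dec <- apo_stop(path, prior_shape, prior_scale, a, b, cost)
    if (dec$truncated) trunc_n <- trunc_n + 1L
    total[i] <- dec$posterior_risk + cost * dec$tau
    tau[i] <- dec$tau
  }
  if (trunc_n > 0.01 * reps)
    warning(sprintf("%d of %d replicates hit the horizon without stopping",
                    trunc_n, reps))
  list(risk = mean(total), mean_tau = mean(tau),
       se = stats::sd(total) / sqrt(reps), n_truncated = trunc_n)
}
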