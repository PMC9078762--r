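# Censored exponential lifetimes: sufficient statistics, likelihood,
# maximum-likelihood and Bayes-LINEX fits, survival/hazard curves.
#
# Data are right-censored pairs (t_i, delta_i), delta_i = 1 for an observed
# failure and 0 for censoring.  The likelihood is lambda^d exp(-lambda T)
# with d = sum(delta) events and T = sum(t) total time at risk, so d and T
# are sufficient; the MLE is d/T and a Gamma(alpha, beta) prior (rate
# convention: beta adds to T) is conjugate, giving posterior
# Gamma(alpha + d, beta + T) and Bayes-LINEX estimate
# ((d + alpha)/a) log(1 + a/(T + beta)).

#' Sufficient statistics of a right-censored sample
#'
#' @param time nonnegative observation times.
#' @param status censoring indicators, 1 = observed failure, 0 = censored.
#' @return List with `d` (number of events) and `total_time` (sum of times).
#' @export
#' @examples
#' censored_summary(c(2, 3, 5), c(1, 1, 0))   # d = 2, total_time = 10
censored_summary <- function(time, status) {
  if (length(time) == 0L) stop("empty sample", call. = FALSE)
  if (length(time) != length(status))
    stop("'time' and 'status' must have the same length", call. = FALSE)
  if (anyNA(time) || anyNA(status)) stop("missing values in sample", call. = FALSE)
  if (any(time < 0)) stop("negative observation time", call. = FALSE)
  if (!all(status %in% c(0, 1))) stop("'status' must be 0 or 1", call. = FALSE)
  list(d = as.integer(sum(status)), total_time = sum(time))
}

#' Censored exponential log-likelihood
#'
#' `d log(lambda) - lambda T` (constant terms dropped); maximized at
#' `lambda = d/T`.
#'
#' @inheritParams censored_summary
#' @param rate positive exponential rate(s), vectorized.
#' @return Log-likelihood values.
#' @export
exp_loglik <- function(time, status, rate) {
  s <- censored_summary(time, status)
  if (any(rate <= 0)) stop("'rate' must be positive", call. = FALSE)
  s$d * log(rate) - rate * s$total_time
}

#' Conjugate gamma posterior for the exponential rate
#'
#' Updates a Gamma(shape, rate) prior (rate convention: the prior rate adds
#' to the total time at risk) with a right-censored exponential sample.
#'
#' @inheritParams censored_summary
#' @param prior_shape,prior_rate gamma prior hyperparameters.
#' @return A [gamma_dist()] with shape `prior_shape + d` and rate
#'   `prior_rate + total_time`.
#' @export
exp_posterior <- function(time, status, prior_shape = 1, prior_rate = 1) {
  s <- censored_summary(time, status)
  check_pos(prior_shape, "prior_shape"); check_pos(prior_rate, "prior_rate")
  gamma_dist(prior_shape + s$d, prior_rate + s$total_time)
}

#' Fit an exponential lifetime model under censoring
#'
#' Fits a constant-hazard (exponential) model to right-censored lifetimes,
#' either by maximum likelihood (`lambda = d/T`) or as the Bayes estimator
#' under LINEX loss from the conjugate gamma posterior,
#' `((d + alpha)/a) log((T + beta + a)/(T + beta))`.  The Bayes-LINEX fit
#' stays below the posterior mean for `a > 0` and tends to it as `a -> 0`;
#' with a diffuse prior and small `|a|` it recovers the MLE.
#'
#' @param x a formula with a [survival::Surv()] response and no covariates
#'   (intercept only), or a numeric vector of times.
#' @param ... further arguments passed on.
#' @return An object of class `"linexp"` with components `lambda` (the rate
#'   estimate), `method`, `d`, `total_time`, `n`, `prior` and `posterior`
#'   ([gamma_dist()]s, Bayes method only), `a`, `b`, `loglik`, the data and
#'   the call.  Methods: `print`, `summary`, `coef`, `logLik`, `predict`,
#'   `residuals` (Cox-Snell), `simulate`, `plot`.
#' @export
#' @examples
#' d <- data.frame(time = c(2, 3, 5), status = c(1, 1, 0))
#' fit <- linexp(survival::Surv(time, status) ~ 1, data = d,
#'               method = "bayes", prior = c(1, 1), a = 1)
#' coef(fit)                         # 3*log(12/11)
#' predict(fit, times = 5)           # fitted survival at t = 5
linexp <- function(x, ...) UseMethod("linexp")

#' @rdname linexp
#' @param data,subset,na.action as in standard modelling functions.
#' @export
linexp.formula <- function(x, data = parent.frame(), subset, na.action, ...) {
  cl <- match.call()
  mf <- match.call(expand.dots = FALSE)
  mf$... <- NULL
  mf[[1L]] <- quote(stats::model.frame)
  names(mf)[names(mf) == "x"] <- "formula"
  mf <- eval(mf, parent.frame())
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv") || attr(y, "type") != "right")
    stop("the response must be a right-censored survival::Surv object",
         call. = FALSE)
  if (length(attr(stats::terms(mf), "term.labels")) > 0L)
    stop("covariates are not supported: the model is intercept-only", call. = FALSE)
  fit <- linexp.default(as.numeric(y[, "time"]), as.numeric(y[, "status"]), ...)
  fit$call <- cl
  fit
}

#' @rdname linexp
#' @param status censoring indicators (default: all observed).
#' @param method `"mle"` or `"bayes"` (Bayes-LINEX).
#' @param prior length-2 vector `c(shape, rate)` of the gamma prior (Bayes
#'   method; rate convention).
#' @param a,b LINEX shape and scale (Bayes method).
#' @export
linexp.default <- function(x, status = NULL, method = c("bayes", "mle"),
                           prior = c(1, 1), a = 1, b = 1, ...) {
  method <- match.arg(method)
  if (is.null(status)) status <- rep(1, length(x))
  s <- censored_summary(x, status)
  if (s$total_time <= 0) stop("total time at risk must be positive", call. = FALSE)
  prior_d <- posterior <- NULL
  if (method == "mle") {
    if (s$d == 0L) {
      warning("no events observed: the MLE is on the boundary (rate 0); ",
              "consider the Bayes-LINEX fit")
      lambda <- 0
    } else lambda <- s$d / s$total_time
  } else {
    check_linex(a, b)
    if (length(prior) != 2L) stop("'prior' must be c(shape, rate)", call. = FALSE)
    prior_d <- gamma_dist(prior[1], prior[2])
    posterior <- gamma_dist(prior_d$shape + s$d, prior_d$rate + s$total_time)
    lambda <- bayes_estimate_gamma(posterior$shape, posterior$rate, a)
  }
  structure(list(
    lambda = lambda, method = method,
    d = s$d, total_time = s$total_time, n = length(x),
    prior = prior_d, posterior = posterior,
    a = if (method == "bayes") a, b = if (method == "bayes") b,
    loglik = if (lambda > 0) s$d * log(lambda) - lambda * s$total_time else {
      if (s$d == 0L) 0 else -Inf
    },
    time = as.numeric(x), status = as.numeric(status),
    call = match.call()), class = "linexp")
}

#' @export
print.linexp <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  cat("Censored exponential fit (",
      if (x$method == "mle") "maximum likelihood" else
        sprintf("Bayes-LINEX, a = %g, b = %g", x$a, x$b),
      ")\n", sep = "")
  cat(sprintf("  n = %d, events = %d, total time at risk = %g\n",
              x$n, x$d, x$total_time))
  cat(sprintf("  rate (constant hazard): %s\n", format(x$lambda, digits = digits)))
  invisible(x)
}

#' @export
coef.linexp <- function(object, ...) c(rate = object$lambda)

#' @export
logLik.linexp <- function(object, ...) {
  structure(object$loglik, df = 1L, nobs = object$n, class = "logLik")
}

#' @export
summary.linexp <- function(object, ...) {
  out <- object
  if (object$method == "mle") {
    out$se <- if (object$d > 0) object$lambda / sqrt(object$d) else NA_real_
  } else {
    out$posterior_mean <- mean(object$posterior)
    out$posterior_sd <- sqrt(object$posterior$shape) / object$posterior$rate
    out$posterior_risk <- posterior_linex_risk_gamma(
      object$posterior$shape, object$posterior$rate, object$a, object$b)
  }
  class(out) <- c("summary.linexp", "linexp")
  out
}

#' @export
print.summary.linexp <- function(x, digits = max(4L, getOption("digits") - 3L), ...) {
  print.linexp(x, digits = digits, ...)
  if (x$method == "mle") {
    cat(sprintf("  se(rate) = %s (observed information)\n",
                format(x$se, digits = digits)))
  } else {
    cat(sprintf("  posterior: Gamma(shape %g, rate %g); mean %s, sd %s\n",
                x$posterior$shape, x$posterior$rate,
                format(x$posterior_mean, digits = digits),
                format(x$posterior_sd, digits = digits)))
    cat(sprintf("  posterior LINEX risk at the Bayes estimate: %s\n",
                format(x$posterior_risk, digits = digits)))
  }
  cat(sprintf("  log-likelihood: %s\n", format(x$loglik, digits = digits)))
  invisible(x)
}

#' Fitted survival, hazard or density of a censored exponential fit
#'
#' Survival `exp(-lambda t)` (1 at `t = 0`, strictly decreasing), constant
#' hazard `lambda`, or density `lambda exp(-lambda t)`.
#'
#' @param object a [linexp()] fit.
#' @param times nonnegative evaluation times.
#' @param type `"survival"`, `"hazard"` or `"density"`.
#' @param ... unused.
#' @return Numeric vector along `times`.
#' @export
predict.linexp <- function(object, times,
                           type = c("survival", "hazard", "density"), ...) {
  type <- match.arg(type)
  if (missing(times)) times <- sort(object$time)
  if (any(times < 0)) stop("'times' must be nonnegative", call. = FALSE)
  switch(type,
         survival = exp(-object$lambda * times),
         hazard = rep(object$lambda, length(times)),
         density = object$lambda * exp(-object$lambda * times))
}

#' @export
residuals.linexp <- function(object, ...) {
  # Cox-Snell residuals: lambda*t_i are censored unit-exponential if the
  # model holds
  r <- object$lambda * object$time
  attr(r, "status") <- object$status
  r
}

#' @export
simulate.linexp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cf <- 1 - object$d / object$n   # observed censoring fraction
  replicate(nsim, gen_censored_exponential(object$n, object$lambda, cf),
            simplify = FALSE)
}

#' @export
plot.linexp <- function(x, xlab = "time", ylab = "survival", km = TRUE, ...) {
  tmax <- max(x$time)
  grid <- seq(0, tmax * 1.05, length.out = 200)
  plot(grid, predict(x, grid), type = "l", xlab = xlab, ylab = ylab,
       ylim = c(0, 1), ...)
  if (km && x$d > 0) {
    sf <- survival::survfit(survival::Surv(x$time, x$status) ~ 1)
    graphics::lines(sf$time, sf$surv, type = "s", lty = 2)
    graphics::legend("topright", c("fitted", "Kaplan-Meier"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}
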