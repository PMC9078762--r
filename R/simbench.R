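# Synthetic-data generators and the Monte-Carlo benchmark harness that
# compares estimators by bias, MSE and LINEX risk (the structure of the
# survival/hazard comparison tables), plus CSV round-tripping of the
# resulting risk tables.

#' Generate a right-censored exponential sample
#'
#' Lifetimes are Exp(`rate`); censoring times are independent Exp with rate
#' `rate * q/(1-q)` so that the expected censoring fraction equals `q`
#' (`q = 0` disables censoring).
#'
#' @param n sample size.
#' @param rate positive true failure rate.
#' @param censor_fraction target expected censoring fraction in `[0, 1)`.
#' @param seed optional integer seed (RNG untouched if `NULL`).
#' @return `data.frame` with columns `time` and `status`.
#' @export
gen_censored_exponential <- function(n, rate, censor_fraction = 0, seed = NULL) {
  check_count(n); check_pos(rate, "rate")
  if (censor_fraction < 0 || censor_fraction >= 1)
    stop("'censor_fraction' must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rexp(n, rate)
  if (censor_fraction == 0)
    return(data.frame(time = x, status = rep(1, n)))
  cens <- stats::rexp(n, rate * censor_fraction / (1 - censor_fraction))
  data.frame(time = pmin(x, cens), status = as.numeric(x <= cens))
}

#' Generate a normal sample with its shrinkage summary
#'
#' @param n sample size (`>= 2`).
#' @param mean,sd true mean and standard deviation (`sd > 0`).
#' @param seed optional integer seed.
#' @return List with the raw `sample`, `n`, `xbar`, `d2` (unbiased sample
#'   variance) and `v = sd/mean` (the known coefficient of variation;
#'   requires `mean != 0`).
#' @export
gen_normal <- function(n, mean, sd, seed = NULL) {
  check_count(n, least = 2L); check_pos(sd, "sd")
  if (mean == 0)
    stop("'mean' must be nonzero (the coefficient of variation is undefined)",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n, mean, sd)
  list(sample = x, n = n, xbar = mean(x), d2 = stats::var(x), v = sd / mean)
}

new_risk_table <- function(df, ...) {
  stopifnot(all(c("estimator", "quantity", "bias", "mse", "linex_risk",
                  "se") %in% names(df)))
  ok <- !is.na(df$mse)
  stopifnot(all(df$mse[ok] >= 0), all(df$se[ok] >= 0))
  out <- structure(df, class = c("risk_table", "data.frame"))
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Monte-Carlo bias/MSE/LINEX-risk study for censored exponential fits
#'
#' For each replicate, generates a right-censored exponential sample, fits
#' the rate by maximum likelihood and by Bayes-LINEX, and records the rate,
#' the (constant) hazard and the survival curve on `t_grid`.  Replicates
#' with no observed events are dropped and counted.  When
#' `lambda_from_prior = TRUE` the true rate of each replicate is drawn from
#' the generating gamma prior, so the averaged LINEX risk is a prior
#' (Bayes) risk and the Bayes-LINEX estimator is optimal by construction.
#'
#' A single root seed spawns one sub-seed per replicate, so increasing
#' `reps` extends a run without reshuffling earlier replicates.
#'
#' @param true_lambda true failure rate (ignored when `lambda_from_prior`).
#' @param n sample size per replicate.
#' @param censor_fraction target expected censoring fraction.
#' @param prior_shape,prior_rate gamma prior (rate convention).
#' @param a,b LINEX shape and scale.
#' @param reps number of replicates (`>= 100`).
#' @param seed integer root seed.
#' @param t_grid survival evaluation times; defaults to the deciles of the
#'   true lifetime distribution (prior-mean rate when `lambda_from_prior`).
#' @param lambda_from_prior draw each replicate's rate from the prior?
#' @return A `risk_table` data frame (columns `estimator`, `quantity`,
#'   `bias`, `mse`, `linex_risk`, `se`) with attributes `n_dropped`,
#'   `reps_used`, `paired` (mean and s.e. of the per-replicate Bayes-minus-
#'   MLE LINEX loss difference for the rate) and `survival_curves`.
#' @export
mse_study <- function(true_lambda, n, censor_fraction, prior_shape = 1,
                      prior_rate = 1, a = 1, b = 1, reps, seed,
                      t_grid = NULL, lambda_from_prior = FALSE) {
  check_count(reps, least = 100L, what = "reps")
  check_linex(a, b); check_count(n)
  check_pos(prior_shape, "prior_shape"); check_pos(prior_rate, "prior_rate")
  if (is.null(t_grid)) {
    ref_rate <- if (lambda_from_prior) prior_shape / prior_rate else true_lambda
    t_grid <- stats::qexp(seq(0.1, 0.9, by = 0.1), rate = ref_rate)
  }
  set.seed(seed)
  sub <- sample.int(2147483646L, reps)
  lam <- lam_mle <- lam_bl <- rep(NA_real_, reps)
  sb_mle <- sm_mle <- sl_mle <- rep(NA_real_, reps)  # survival bias/mse/loss
  sb_bl <- sm_bl <- sl_bl <- rep(NA_real_, reps)
  surv_sum <- matrix(0, 3, length(t_grid))  # true, mle, bayes means
  dropped <- 0L
  for (i in seq_len(reps)) {
    set.seed(sub[i])
    li <- if (lambda_from_prior)
      stats::rgamma(1, shape = prior_shape, rate = prior_rate) else true_lambda
    samp <- gen_censored_exponential(n, li, censor_fraction)
    d <- sum(samp$status); tt <- sum(samp$time)
    if (d == 0L) { dropped <- dropped + 1L; next }
    lam[i] <- li
    lam_mle[i] <- d / tt
    lam_bl[i] <- bayes_estimate_gamma(prior_shape + d, prior_rate + tt, a)
    s_true <- exp(-li * t_grid)
    s_mle <- exp(-lam_mle[i] * t_grid)
    s_bl <- exp(-lam_bl[i] * t_grid)
    surv_sum <- surv_sum + rbind(s_true, s_mle, s_bl)
    sb_mle[i] <- mean(s_mle - s_true); sm_mle[i] <- mean((s_mle - s_true)^2)
    sl_mle[i] <- mean(linex_loss(s_mle, s_true, a, b))
    sb_bl[i] <- mean(s_bl - s_true); sm_bl[i] <- mean((s_bl - s_true)^2)
    sl_bl[i] <- mean(linex_loss(s_bl, s_true, a, b))
  }
  keep <- !is.na(lam)
  m <- sum(keep)
  if (m == 0L) stop("all replicates degenerate (no events)", call. = FALSE)
  row <- function(est, qty, err, loss) {
    data.frame(estimator = est, quantity = qty,
               bias = mean(err), mse = mean(err^2), linex_risk = mean(loss),
               se = stats::sd(err^2) / sqrt(m))
  }
  e_mle <- lam_mle[keep] - lam[keep]
  e_bl <- lam_bl[keep] - lam[keep]
  l_mle <- linex_loss(lam_mle[keep], lam[keep], a, b)
  l_bl <- linex_loss(lam_bl[keep], lam[keep], a, b)
  tab <- rbind(
    row("mle", "lambda", e_mle, l_mle),
    row("bayes_linex", "lambda", e_bl, l_bl),
    row("mle", "hazard", e_mle, l_mle),
    row("bayes_linex", "hazard", e_bl, l_bl),
    data.frame(estimator = "mle", quantity = "survival",
               bias = mean(sb_mle[keep]), mse = mean(sm_mle[keep]),
               linex_risk = mean(sl_mle[keep]),
               se = stats::sd(sm_mle[keep]) / sqrt(m)),
    data.frame(estimator = "bayes_linex", quantity = "survival",
               bias = mean(sb_bl[keep]), mse = mean(sm_bl[keep]),
               linex_risk = mean(sl_bl[keep]),
               se = stats::sd(sm_bl[keep]) / sqrt(m)))
  curves <- data.frame(t = t_grid,
                       survival_true = surv_sum[1, ] / m,
                       survival_mle = surv_sum[2, ] / m,
                       survival_bayes = surv_sum[3, ] / m)
  diff <- l_bl - l_mle
  new_risk_table(tab, n_dropped = dropped, reps_used = m,
                 paired = list(linex_diff_mean = mean(diff),
                               linex_diff_se = stats::sd(diff) / sqrt(m)),
                 survival_curves = curves)
}

#' Benchmark configuration
#'
#' Bundles a benchmark scenario with its parameters, replication count and
#' seed for [run_benchmark()].
#'
#' @param scenario one of `"exp_survival"`, `"normal_shrinkage"`,
#'   `"ned_shrinkage"`, `"poisson_apo"`.
#' @param reps replicates (`>= 100`).
#' @param seed integer seed.
#' @param ... scenario parameters, passed through (see [run_benchmark()]).
#' @return An object of class `"bench_config"`.
#' @export
bench_config <- function(scenario = c("exp_survival", "normal_shrinkage",
                                      "ned_shrinkage", "poisson_apo"),
                         reps, seed, ...) {
  scenario <- match.arg(scenario)
  check_count(reps, least = 100L, what = "reps")
  check_count(seed, least = 0L, what = "seed")
  structure(list(scenario = scenario, reps = as.integer(reps),
                 seed = as.integer(seed), params = list(...)),
            class = "bench_config")
}

# invariant-LINEX comparison of scaled estimators coef * stat for a scale
# parameter `truth`, shared by the normal and NED scenarios (internal)
scaled_estimator_rows <- function(stat, truth, coefs, quantity, a, b) {
  m <- length(stat)
  do.call(rbind, lapply(names(coefs), function(nm) {
    est <- coefs[[nm]] * stat
    err <- est - truth
    loss <- invariant_linex_loss(est, truth, a, b)
    data.frame(estimator = nm, quantity = quantity,
               bias = mean(err), mse = mean(err^2), linex_risk = mean(loss),
               se = stats::sd(err^2) / sqrt(m))
  }))
}

#' Run a benchmark scenario
#'
#' Dispatches a [bench_config()] to its scenario and aggregates bias, MSE
#' and LINEX risk with standard errors.
#'
#' Scenario parameters (supplied as `...` of [bench_config()]):
#' \describe{
#' \item{exp_survival}{`true_lambda`, `n`, `censor_fraction`, `prior_shape`,
#'   `prior_rate`, `a`, `b`, `t_grid`, `lambda_from_prior` — see
#'   [mse_study()].}
#' \item{normal_shrinkage}{`mu`, `sigma`, `n`, `a`, `b`: compares the sample
#'   mean, the MSE-optimal shrinkage `n/(n+v^2)*abar` and the LINEX-optimal
#'   shrinkage under invariant LINEX risk.}
#' \item{ned_shrinkage}{`theta`, `n`, `a`, `b`: same comparison for the
#'   negative-exponential scale.}
#' \item{poisson_apo}{`prior_shape`, `prior_scale`, `a`, `b`, `costs`
#'   (vector), `horizon`: total Bayes risk and mean stopping time of the APO
#'   rule per cost.}
#' }
#'
#' @param config a [bench_config()].
#' @return A `risk_table` data frame.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "bench_config"))
  p <- config$params
  a <- if (is.null(p$a)) 1 else p$a
  b <- if (is.null(p$b)) 1 else p$b
  switch(config$scenario,
    exp_survival = {
      args <- p[names(p) %in% c("true_lambda", "n", "censor_fraction",
                                "prior_shape", "prior_rate", "a", "b",
                                "t_grid", "lambda_from_prior")]
      do.call(mse_study, c(args, list(reps = config$reps, seed = config$seed)))
    },
    normal_shrinkage = {
      check_pos(p$sigma, "sigma"); check_count(p$n)
      if (p$mu <= 0) stop("'mu' must be positive for invariant risk", call. = FALSE)
      v <- p$sigma / p$mu
      set.seed(config$seed)
      abar <- stats::rnorm(config$reps, p$mu, p$sigma / sqrt(p$n))
      coefs <- list(sample_mean = 1,
                    mse_opt = optimal_shrink_mean_mse(p$n, v)$s,
                    linex_opt = optimal_shrink_mean_linex(p$n, v, a, b)$z_min)
      new_risk_table(scaled_estimator_rows(abar, p$mu, coefs, "mean", a, b),
                     reps_used = config$reps)
    },
    ned_shrinkage = {
      check_pos(p$theta, "theta"); check_count(p$n)
      set.seed(config$seed)
      abar <- stats::rgamma(config$reps, shape = p$n, rate = p$n / p$theta)
      coefs <- list(sample_mean = 1,
                    mse_opt = shrink_scale_mse(p$n)$s,
                    linex_opt = optimal_shrink_scale_linex(p$n, a))
      new_risk_table(scaled_estimator_rows(abar, p$theta, coefs, "scale", a, b),
                     reps_used = config$reps)
    },
    poisson_apo = {
      costs <- p$costs
      if (is.null(costs)) stop("'costs' required for the poisson_apo scenario",
                               call. = FALSE)
      rows <- do.call(rbind, lapply(seq_along(costs), function(j) {
        r <- sequential_bayes_risk(p$prior_shape, p$prior_scale, a, b,
                                   cost = costs[j], reps = config$reps,
                                   seed = config$seed + j - 1L,
                                   horizon = p$horizon)
        data.frame(estimator = "apo_rule",
                   quantity = sprintf("cost=%g", costs[j]),
                   bias = NA_real_, mse = NA_real_,
                   linex_risk = r$risk, se = r$se, mean_tau = r$mean_tau)
      }))
      new_risk_table(rows, reps_used = config$reps)
    })
}

#' Write / read a risk table as CSV
#'
#' Plain headered CSV with numbers at full double precision (round-trips
#' losslessly well beyond 12 significant digits).
#'
#' @param x a `risk_table` (any data frame works).
#' @param file path to the CSV file.
#' @return `read_risk_table` returns the `risk_table`;
#'   `write_risk_table` returns `file` invisibly.
#' @export
write_risk_table <- function(x, file) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) format(col, digits = 17, trim = TRUE))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_risk_table
#' @export
read_risk_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  structure(df, class = c("risk_table", "data.frame"))
}
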