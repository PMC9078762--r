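test_that("poisson_path validates its invariants", {
  expect_error(poisson_path(c(2, 1), 5), "increasing")
  expect_error(poisson_path(c(1, 6), 5), "\\[0, horizon\\]")
  p <- poisson_path(c(0.5, 2), 3)
  expect_equal(n_events(p, c(0, 1, 2, 3)), c(0L, 1L, 2L, 2L))
  expect_error(n_events(p, 4), "horizon")
})

test_that("simulated paths have Poisson counts and exponential gaps", {
  set.seed(19)
  counts <- vapply(1:2000, function(i)
    length(simulate_poisson_path(2, 5)$event_times), 0L)
  se <- sd(counts) / sqrt(2000)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  # inter-event gaps: first two moments of Exp(theta)
  gaps <- unlist(lapply(1:500, function(i)
    diff(c(0, simulate_poisson_path(2, 50)$event_times))))
  expect_lt(abs(mean(gaps) - 0.5), 3 * sd(gaps) / sqrt(length(gaps)))
  expect_equal(sd(gaps) / mean(gaps), 1, tolerance = 0.05)
  # determinism under seed
  p1 <- simulate_poisson_path(1, 10, seed = 4)
  p2 <- simulate_poisson_path(1, 10, seed = 4)
  expect_identical(p1$event_times, p2$event_times)
})

test_that("conjugate updating of the intensity posterior (scale convention)", {
  p <- poisson_path(c(0.5, 2.0), 5)
  expect_equal(poisson_posterior(1, 1, p, 0),
               gamma_dist(1, 1), ignore_attr = TRUE)
  post <- poisson_posterior(1, 1, p, 1)
  expect_equal(post$shape, 2)
  expect_equal(post$rate, 2)
  # quadrature: posterior matches normalized likelihood x prior
  unnorm <- function(th) th^1 * exp(-th * 1) * dgamma(th, 1, scale = 1)
  nc <- integrate(unnorm, 0, Inf, rel.tol = 1e-12)$value
  l1 <- integrate(function(th) abs(unnorm(th) / nc - dgamma(th, 2, 2)),
                  0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
  expect_lt(l1, 1e-8)
})

test_that("sequential estimate and risk equal the generic gamma machinery", {
  expect_equal(theta_tilde(1, 1, poisson_path(numeric(0), 5), 0, a = 1), log(2))
  expect_equal(posterior_risk_u(1, 1, poisson_path(numeric(0), 5), 0, a = 1),
               1 - log(2))
  set.seed(23)
  for (i in 1:25) {
    al <- runif(1, 0.5, 4); be <- runif(1, 0.2, 3)
    path <- simulate_poisson_path(runif(1, 0.5, 3), 10)
    t0 <- runif(1, 0, 10); a <- sample(c(-0.3, 0.5, 1, 2), 1)
    post <- poisson_posterior(al, be, path, t0)
    expect_equal(posterior_risk_u(al, be, path, t0, a),
                 posterior_linex_risk_gamma(post$shape, post$rate, a),
                 tolerance = 1e-12)
    expect_equal(theta_tilde(al, be, path, t0, a),
                 bayes_estimate_gamma(post$shape, post$rate, a),
                 tolerance = 1e-12)
  }
  # oracle equality on one posterior
  path <- simulate_poisson_path(1, 10, seed = 6)
  post <- poisson_posterior(2, 0.5, path, 7)
  expect_equal(theta_tilde(2, 0.5, path, 7, a = 1),
               numeric_bayes_oracle(function(x) dgamma(x, post$shape, post$rate),
                                    a = 1),
               tolerance = 1e-6)
})

test_that("U_t decreases between events, jumps at events; a->0 variance limit", {
  path <- poisson_path(c(1, 3, 4.5), 10)
  tt <- seq(0, 0.999, length.out = 50)
  u <- vapply(tt, function(t) posterior_risk_u(2, 1, path, t, a = 1), 0)
  expect_true(all(diff(u) < 0))
  just_before <- posterior_risk_u(2, 1, path, 3 - 1e-9, a = 1)
  at_event <- posterior_risk_u(2, 1, path, 3, a = 1)
  expect_gt(at_event, just_before)
  # squared-error limit: U_t / (a^2/2) -> posterior variance
  a <- 1e-5
  post <- poisson_posterior(2, 1, path, 5)
  expect_equal(posterior_risk_u(2, 1, path, 5, a) / (a^2 / 2),
               post$shape / post$rate^2, tolerance = 1e-4)
})

test_that("the APO rule stops where posterior risk crosses the cost line", {
  # empty path, alpha = beta = 1, a = 1, c = 0.1: root of the scalar equation
  g <- function(t) (1 / (t + 1) - log1p(1 / (t + 1))) - 0.1 * t
  tau_oracle <- uniroot(g, c(0.1, 5), tol = 1e-12)$root
  dec <- apo_stop(poisson_path(numeric(0), 5), 1, 1, a = 1, cost = 0.1)
  expect_equal(dec$tau, tau_oracle, tolerance = 1e-8)
  expect_false(dec$truncated)
  expect_lt(abs(dec$posterior_risk - 0.1 * dec$tau), 1e-9)
  # tau is nonincreasing in the cost
  path <- simulate_poisson_path(2, 200, seed = 31)
  taus <- vapply(c(0.001, 0.01, 0.1, 1), function(cc)
    apo_stop(path, 1.5, 1, a = 1, cost = cc)$tau, 0)
  expect_true(all(diff(taus) <= 0))
  # interior stops satisfy the root condition tightly
  for (cc in c(0.005, 0.05, 0.5)) {
    d <- apo_stop(path, 2, 0.7, a = 0.8, cost = cc)
    expect_false(d$truncated)
    expect_lt(abs(d$posterior_risk - cc * d$tau), 1e-9)
  }
  # no crossing before a short horizon: truncation is flagged
  d_tr <- apo_stop(poisson_path(numeric(0), 0.05), 1, 1, a = 1, cost = 1e-4)
  expect_true(d_tr$truncated)
  expect_equal(d_tr$tau, 0.05)
})

test_that("U_t - c*t changes sign at most once per inter-event interval", {
  path <- simulate_poisson_path(1.5, 30, seed = 41)
  cc <- 0.02
  ev <- c(0, path$event_times, path$horizon)
  for (i in seq_len(length(ev) - 1L)) {
    if (ev[i + 1] - ev[i] < 1e-9) next
    tt <- seq(ev[i], ev[i + 1] - 1e-9, length.out = 25)
    g <- vapply(tt, function(t)
      posterior_risk_u(1, 1, path, t, a = 1) - cc * t, 0)
    expect_lte(sum(diff(sign(g)) != 0), 1)
  }
})

test_that("scaled risk C_t approaches a^2*theta/2 and scales in a^2", {
  set.seed(47)
  horizons <- c(100, 1000)
  err <- vapply(horizons, function(h) {
    ct <- vapply(1:60, function(i) {
      path <- simulate_poisson_path(1, h)
      scaled_risk_c(1, 1, path, h, a = 1)
    }, 0)
    abs(mean(ct) - 0.5)
  }, 0)
  expect_lt(err[2], err[1])   # error shrinks with t
  expect_lt(err[2], 0.05)
  # a = 0.5 quarter-scales the asymptote
  ct5 <- vapply(1:60, function(i) {
    path <- simulate_poisson_path(1, 1000)
    scaled_risk_c(1, 1, path, 1000, a = 0.5)
  }, 0)
  expect_equal(mean(ct5), 0.125, tolerance = 0.05)
})

test_that("sequential Bayes risk decreases with the sampling cost", {
  risks <- vapply(c(0.1, 0.01), function(cc)
    sequential_bayes_risk(2, 1, a = 1, cost = cc, reps = 150, seed = 5,
                          horizon = 60)$risk, 0)
  expect_true(all(risks > 0))
  expect_lt(risks[2], risks[1])
})
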