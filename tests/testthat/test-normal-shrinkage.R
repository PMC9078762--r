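test_that("MSE-optimal mean shrinkage matches the closed form and a brute-force minimizer", {
  res <- optimal_shrink_mean_mse(4, 1)
  expect_equal(res$s, 0.8)
  expect_equal(optimal_shrink_mean_mse(10, 1)$relative_mse, 0.1 / 1.1)
  expect_lt(optimal_shrink_mean_mse(10, 1)$relative_mse, 0.1)
  # v -> 0: no shrinkage
  expect_equal(optimal_shrink_mean_mse(5, 1e-8)$s, 1, tolerance = 1e-8)
  # brute force: minimize the empirical MSE over s on shared draws
  set.seed(101)
  mu <- 2; v <- 1; n <- 4
  abar <- rnorm(2e5, mu, mu * v / sqrt(n))
  emp <- function(s) mean((s * abar - mu)^2)
  s_hat <- optimize(emp, c(0.2, 1.5), tol = 1e-9)$minimum
  expect_equal(s_hat, res$s, tolerance = 0.02)
})

test_that("exact invariant LINEX risk of z*abar matches formula, Monte Carlo, and is convex", {
  expect_equal(invariant_risk_mean(1, 10, 1, a = 0.5), exp(0.0125) - 1)
  expect_equal(invariant_risk_mean(1, 10, 1e-9, a = 0.5), 0, tolerance = 1e-9)
  z <- seq(0.2, 1.4, by = 0.02)
  r <- invariant_risk_mean(z, 8, 2, a = 0.4)
  expect_true(all(diff(r, differences = 2) > 0))
  # Monte-Carlo expectation of the invariant loss over simulated abar
  set.seed(21)
  n <- 10; v <- 1; mu <- 3; a <- 0.5; z0 <- 0.9
  abar <- rnorm(2e5, mu, mu * v / sqrt(n))
  mc <- mean(invariant_linex_loss(z0 * abar, mu, a))
  se <- sd(invariant_linex_loss(z0 * abar, mu, a)) / sqrt(2e5)
  expect_lt(abs(mc - invariant_risk_mean(z0, n, v, a)), 3 * se)
})

test_that("LINEX-optimal mean shrinkage: numeric optimum, truncated closed form, limits", {
  for (cfg in list(c(5, 2, 0.2), c(10, 2, 0.4), c(20, 2.5, 0.6))) {
    n <- cfg[1]; v <- cfg[2]; a <- cfg[3]
    res <- optimal_shrink_mean_linex(n, v, a)
    expect_gt(res$z_min, 0); expect_lt(res$z_min, 1)
    # z_min is where an independent golden-section minimizer lands
    z_opt <- optimize(function(z) invariant_risk_mean(z, n, v, a),
                      c(1e-6, 1.5), tol = 1e-10)$minimum
    expect_equal(res$z_min, z_opt, tolerance = 1e-6)
    # truncated closed form is close for small a
    expect_equal(res$z_approx, res$z_min, tolerance = 0.05)
  }
  # a -> 0 recovers the MSE-optimal coefficient
  res0 <- optimal_shrink_mean_linex(10, 1, a = 1e-7)
  expect_equal(res0$z_min, 10 / 11, tolerance = 1e-6)
  expect_equal(res0$z_approx, 10 / 11, tolerance = 1e-6)
})

test_that("MVUE of mu^2 is the stated statistic and unbiased in simulation", {
  expect_equal(mvue_mu2(0, 4, 4), -1)
  expect_equal(mvue_mu2(2, 4, 4), 3)
  set.seed(33)
  n <- 5; mu <- 1.5; sigma <- 2
  reps <- 1e5
  x <- matrix(rnorm(n * reps, mu, sigma), nrow = n)
  est <- colMeans(x)^2 - apply(x, 2, var) / n
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - mu^2), 3 * se)
})

test_that("MSE-optimal mu^2 shrinkage matches exact moments and brute force", {
  expect_equal(optimal_shrink_mu2_mse(10, 1), 1.1 / 1.63)
  expect_equal(optimal_shrink_mu2_mse(7, 1e-8), 1, tolerance = 1e-7)
  expect_lt(optimal_shrink_mu2_mse(10, 2), 1)
  set.seed(55)
  n <- 10; v <- 1; mu <- 2
  abar2 <- rnorm(2e5, mu, mu * v / sqrt(n))^2
  emp <- function(t) mean((t * abar2 - mu^2)^2)
  t_hat <- optimize(emp, c(0.2, 1.2), tol = 1e-9)$minimum
  expect_equal(t_hat, 1.1 / 1.63, tolerance = 0.03)
})

test_that("exact invariant risk of t*abar^2 is validated and its optimum behaves", {
  n <- 20; v <- 1; a <- 0.05
  tr <- invariant_risk_mu2(0.8, n, v, a, truncated = TRUE)
  ex <- invariant_risk_mu2(0.8, n, v, a)
  expect_lt(abs(tr - ex) / ex, a)   # truncation error is O(a) relative
  # Monte-Carlo check of the exact risk
  set.seed(77)
  mu <- 1.5; n <- 10; v <- 1; a <- 0.2; t0 <- 0.7
  abar <- rnorm(5e5, mu, mu * v / sqrt(n))
  loss <- invariant_linex_loss(t0 * abar^2, mu^2, a)
  expect_lt(abs(mean(loss) - invariant_risk_mu2(t0, n, v, a)),
            3 * sd(loss) / sqrt(5e5))
  # MGF domain guard
  expect_error(invariant_risk_mu2(3, 5, 2, a = 1), "MGF")
  # optimum: limits and bounds
  res <- optimal_shrink_mu2_linex(10, 1, a = 0.2)
  expect_gt(res$t4_min, 0); expect_lt(res$t4_min, 1)
  expect_equal(optimal_shrink_mu2_linex(10, 1, a = 1e-7)$t4_min,
               optimal_shrink_mu2_mse(10, 1), tolerance = 1e-5)
  expect_equal(res$t4_approx, res$t4_min, tolerance = 0.02)
})

test_that("variance-divisor MSE reproduces the unbiased value and is minimized at n+1", {
  expect_equal(sigma2_divisor_mse(5, 4), 0.5)
  expect_equal(sigma2_divisor_mse(5, 6), 1 / 3)
  for (n in c(3, 5, 12)) {
    d_opt <- optimize(function(d) sigma2_divisor_mse(n, d), c(1, 4 * n),
                      tol = 1e-9)$minimum
    expect_equal(d_opt, n + 1, tolerance = 1e-6)
    expect_equal(sigma2_divisor_mse(n, n + 1), 2 / (n + 1))
  }
})

test_that("relative efficiency of the LINEX-optimal vs MSE-optimal mean estimator is >= 1", {
  for (n in c(5, 10, 15, 20)) for (v in c(2, 2.25, 2.5)) for (a in c(0.2, 0.4, 0.6)) {
    z_lin <- optimal_shrink_mean_linex(n, v, a)$z_min
    z_mse <- optimal_shrink_mean_mse(n, v)$s
    ratio <- invariant_risk_mean(z_mse, n, v, a) /
      invariant_risk_mean(z_lin, n, v, a)
    expect_gte(ratio, 1)
  }
})
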