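# Shared fixtures, built in code.

# the worked censored sample: lifetimes 2, 3, 5 with the 5 censored
worked_sample <- list(time = c(2, 3, 5), status = c(1, 1, 0))

# seeded random gamma posteriors for oracle-equivalence loops
random_gamma_posteriors <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(shape = runif(n, 0.5, 8), rate = runif(n, 0.2, 5))
}

# Monte-Carlo mean of abar for an NED(theta) sample, one column per replicate
ned_abar_draws <- function(reps, n, theta, seed) {
  set.seed(seed)
  colMeans(matrix(rexp(n * reps, rate = 1 / theta), nrow = n))
}
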