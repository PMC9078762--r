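# linexbayes

Estimation of scale-type parameters under the asymmetric **LINEX**
(linear-exponential) loss

L(Δ) = b (e^{aΔ} − aΔ − 1),   Δ = θ̂ − θ,  a ≠ 0, b > 0,

for which overestimation (a > 0) is exponentially more expensive than
underestimation — the relevant asymmetry when, say, a survival probability
must not be overstated.  The package is aimed at biostatisticians and
reliability analysts who want the Bayes answer under this loss next to the
usual maximum-likelihood and minimum-MSE answers, with the Monte-Carlo
machinery to compare them.

It provides four connected pieces:

1. **LINEX core** — the loss in plain and invariant (relative-error) form;
   the closed-form Bayes estimator for a Gamma(k, r) posterior,
   θ̃ = (k/a) log(1 + a/r), with its attained posterior risk
   b·k·(a/r − log(1 + a/r)); and a quadrature oracle
   (`numeric_bayes_oracle()`) that recovers the same minimizer for an
   arbitrary posterior density, used throughout the tests as an independent
   check.
2. **Censored exponential lifetimes** — `linexp()` fits a constant-hazard
   model to right-censored data by ML (λ̂ = d/T) or as the Bayes-LINEX
   estimator from the conjugate Gamma(α + d, β + T) posterior, with
   `print`, `summary`, `coef`, `logLik`, `predict` (survival/hazard),
   `residuals` (Cox–Snell), `simulate` and `plot` methods, and a
   formula/`survival::Surv` interface.
3. **Shrinkage estimators** — minimum-MSE and minimum-invariant-LINEX-risk
   coefficients for z·ā (normal mean with known coefficient of variation
   v = σ/μ; negative-exponential scale) and t·ā² (μ² and θ²), from exact
   moment-generating-function risks, with the cubic-truncated closed forms
   validated against numeric minimizers.  E.g. s = n/(n+v²) (normal, MSE),
   z_min = (n/a)(1 − e^{−a/(n+1)}) (NED, LINEX).
4. **APO sequential rule** — for a homogeneous Poisson process of intensity
   θ under a Gamma(shape, scale) prior with sampling cost c per unit time,
   the asymptotically pointwise optimal stopping time
   τ* = inf{t : U_t ≤ c·t}, where U_t is the posterior LINEX risk, plus
   Monte-Carlo evaluation of the total Bayes risk E[U_τ + c·τ].

A seeded benchmark harness (`mse_study()`, `run_benchmark()`) compares
estimators by bias, MSE and LINEX risk and round-trips its tables through
CSV; `exec/linexbayes` is a thin command-line front end over the same
functions.

## Worked example

```r
library(linexbayes)
d <- data.frame(time = c(2, 3, 5), status = c(1, 1, 0))  # 5 is censored
fit <- linexp(survival::Surv(time, status) ~ 1, data = d,
              method = "bayes", prior = c(1, 1), a = 1)
summary(fit)
#> Censored exponential fit (Bayes-LINEX, a = 1, b = 1)
#>   n = 3, events = 2, total time at risk = 10
#>   rate (constant hazard): 0.261
#>   posterior: Gamma(shape 3, rate 11); mean 0.2727, sd 0.1575
#>   posterior LINEX risk at the Bayes estimate: 0.01169
#>   log-likelihood: -5.297
```

With d = 2 events in T = 10 time units and a Gamma(1, 1) prior, the
posterior is Gamma(3, 11); the Bayes-LINEX rate 3·log(12/11) ≈ 0.261 sits
below the posterior mean 3/11 ≈ 0.273 (overestimating the hazard is the
expensive direction at a = 1), while the MLE would be 2/10 = 0.2.  Fitted
survival probabilities:

```r
predict(fit, times = c(1, 5, 10))
#> [1] 0.77025 0.27113 0.07351
```

The APO rule on a still-empty observation window with a unit-mean prior and
cost 0.1 per unit time stops once the posterior risk drops to the
accumulated cost:

```r
apo_stop(poisson_path(numeric(0), 10), 1, 1, a = 1, cost = 0.1)
#> APO stopping decision
#>   tau = 0.97046 with R(tau) = 0 events
#>   intensity estimate theta~ = 0.41045
#>   posterior risk U = 0.097046, sampling cost c*tau = 0.097046
```

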