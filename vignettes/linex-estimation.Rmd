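---
title: "Estimation under LINEX loss: models, numerics and design choices"
author: "linexbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimation under LINEX loss: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linexbayes)
```

## The loss and why it is asymmetric

The linear-exponential (LINEX) loss of an estimation error $\Delta =
\hat\theta - \theta$ is

$$L(\Delta) = b\,\bigl(e^{a\Delta} - a\Delta - 1\bigr), \qquad a \neq 0,\; b > 0.$$

For $a > 0$ the loss climbs exponentially for overestimation and almost
linearly for underestimation; $a < 0$ reverses the roles.  As $|a| \to 0$,
$L(\Delta) \approx \tfrac{b a^2}{2}\Delta^2$: squared error is the symmetric
limit.  This matters in survival work, where overestimating a survival
probability (or underestimating a hazard) is usually the costlier mistake.

For scale-type parameters the package also provides the *invariant* form,
the same loss applied to the relative error $\Delta^* = \hat\theta/\theta -
1$, so that risks do not depend on the unit of measurement.

Notation: several traditions write the shape as $x$, $z$ or $a$ and the
scale as $y$; the package fixes `(a, b)` everywhere.  Because `b` rescales
every risk without moving any minimizer, it defaults to 1 and appears in the
API only for completeness.

## Bayes estimation from gamma posteriors

If the posterior of a positive parameter $\theta$ is Gamma(shape $k$, rate
$r$), the posterior expected LINEX loss is minimized at

$$\tilde\theta = -\tfrac1a \log E\,[e^{-a\theta}\mid \text{data}]
  = \tfrac{k}{a}\,\log\!\bigl(1 + \tfrac{a}{r}\bigr),$$

finite for $a > -r$, with attained posterior risk $b\,k\,(a/r - \log(1 +
a/r)) \ge 0$.  For $a > 0$ the estimate sits below the posterior mean $k/r$
— the deliberate pessimism that LINEX buys.

Two conjugate situations use this machinery:

* **Censored exponential lifetimes** (`linexp()`): observations $(t_i,
  \delta_i)$ with $\delta_i = 1$ for an observed failure.  The likelihood is
  $\lambda^{d} e^{-\lambda T}$ with $d = \sum\delta_i$, $T = \sum t_i$, the
  MLE is $d/T$, and a Gamma$(\alpha,\beta)$ prior (here $\beta$ is a *rate*:
  it adds to $T$) gives the posterior Gamma$(\alpha + d,\ \beta + T)$.
  Survival is $e^{-\hat\lambda t}$ and the hazard is the constant
  $\hat\lambda$.
* **Poisson intensity observed in continuous time** (`poisson_posterior()`
  and friends): a Gamma(shape $\alpha$, *scale* $\beta$) prior updated by
  $R(t)$ events in $[0, t]$ gives shape $\alpha + R(t)$ and rate $t +
  1/\beta$.

The two modules intentionally use different conventions for $\beta$ — rate
for lifetimes, scale for the Poisson prior — because that is how each
conjugate kernel is naturally written; `scale_to_rate()` converts, and every
function documents which convention it takes.

## Shrinkage estimators with known coefficient of variation

For a normal sample with mean $\mu > 0$, variance $\sigma^2$ and *known*
$v = \sigma/\mu$, estimators of the form $z\bar a$ (for $\mu$) and $t\bar
a^2$ (for $\mu^2$) trade a little bias for variance.  Closed forms:

* MSE-optimal mean coefficient $s = n/(n + v^2)$, relative MSE
  $(1/n)/(1 + v^2/n) < 1/n$;
* MSE-optimal $\mu^2$ coefficient $t_2 = (1+u)/(1 + 6u + 3u^2)$, $u =
  v^2/n$, from the exact normal moments of $\bar a$;
* for the negative exponential (scale $\theta$, where $\bar a \sim$
  Gamma$(n, \theta/n)$): $s = n/(n+1)$ with relative MSE $1/(n+1)$, and the
  exact invariant-LINEX optimum $z_{\min} = (n/a)(1 - e^{-a/(n+1)})$;
* the variance divisor study `sigma2_divisor_mse()`: among
  $\sum(x-\bar a)^2/d$, the unbiased $d = n-1$ has relative MSE $2/(n-1)$
  while $d = n+1$ is optimal with $2/(n+1)$.

Exact LINEX risks are evaluated through moment generating functions ($\bar
a$ normal; $\bar a^2$ a scaled noncentral chi-square; $\bar a$ gamma), which
also exposes their domains: the MGF of $\bar a^2$ requires $a t <
n/(2v^2)$, and for a *squared gamma* mean it diverges for every positive
argument — the package asserts this divergence in its tests, and it is the
reason the $\theta^2$ problem is handled through a truncated risk only.

**Truncation convention.**  The cubic-truncated risk used for the
closed-form optima is the third-order Taylor expansion of the exponential,
$e^u - u - 1 \approx u^2/2 + u^3/6$, taken in expectation with *exact*
moments.  Its stationarity condition is a quadratic in the coefficient;
`solve_shrink_quadratic()` evaluates it in the cancellation-free form, takes
the $-C/B$ limit explicitly as $a \to 0$ (so the squared-error optimum is
recovered exactly), and for the $\theta^2$ problem selects the root inside
the second-order-condition bracket $[(a-1)n^2/(a(n+4)(n+5)),\ 1]$,
preferring the smaller truncated risk if both roots qualify.  Every
truncated closed form is validated against an independent numeric minimizer
of the corresponding exact (or truncated, for $\theta^2$) risk.

**Relative efficiency.**  Where the package compares the LINEX-optimal and
MSE-optimal shrinkage estimators it defines relative efficiency as the ratio
of their invariant-LINEX risks, risk(MSE-optimal)/risk(LINEX-optimal) — a
convention of this package; by construction it is $\ge 1$ on any grid.

## The APO stopping rule

Observing a homogeneous Poisson process with unknown intensity $\theta$
costs $c$ per unit time.  After time $t$ the posterior risk of the Bayes
estimate is

$$U_t = b\,(\alpha + R(t))\,\bigl(s_t - \log(1 + s_t)\bigr), \qquad
  s_t = \frac{a\beta}{t\beta + 1},$$

continuous and decreasing between events, jumping up at each event.  The
asymptotically pointwise optimal rule stops at $\tau^* = \inf\{t \ge 0 :
U_t \le c\,t\}$.  Since $U_t - ct$ is strictly decreasing within an
inter-event interval, each interval holds at most one crossing;
`apo_stop()` scans intervals in order and bisects to machine precision
(the returned stop satisfies $|U_\tau - c\tau| \le 10^{-9}$, typically far
better).  At an event time the posterior is taken right-continuously (the
event counts toward $R$); if $U \le ct$ already holds at an event time, the
rule stops there.  For $t \to \infty$, $t\,U_t \to b a^2\theta/2$, which
yields the small-cost approximation $\tau^* \approx a\sqrt{\theta/(2c)}$
used as a sanity check on the Monte-Carlo stopping times.

For $a < 0$ the asymptotic theory needs shape $> 1$ and scale $< -1/a$;
`apo_stop()` warns rather than errors when this is violated, since the rule
itself remains computable.

## Numerical choices

* **Small $|a|$.**  All closed forms route through `log1p`/`expm1`
  (`(k/a)\,\mathrm{log1p}(a/r)`, `expm1(g) - a(\cdot)`), which keeps the
  $O(a^2)$ risks and the $a \to 0$ limits accurate to near machine
  precision without a separate series branch.  `a = 0` itself is rejected:
  the loss is undefined there, and the squared-error limit is available by
  taking a tiny `a`.
* **Quadrature oracle.**  `numeric_bayes_oracle()` integrates with relative
  tolerance $10^{-12}$, minimizes by Brent search (tolerance $10^{-8}$),
  then polishes the minimizer with a root find on the *quadrature* risk
  derivative $\int a b (e^{a(d-\theta)} - 1)\pi(\theta)\,d\theta$.  The
  polish step is needed because a derivative-free search on a flat risk
  surface can only locate a minimum to about the square root of the
  function tolerance; the root find restores full precision while remaining
  independent of any closed form.  Loss-times-density products are
  evaluated in log space so an exponentially growing loss cannot overflow
  against an underflowing density tail.
* **Degenerate inputs.**  All-censored samples ($d = 0$): the MLE is a
  boundary case, reported as rate 0 with a warning, while the Bayes-LINEX
  fit remains proper through the prior — one of the practical arguments for
  the Bayes route.  Empty Poisson paths are valid (the prior is the
  posterior at $t = 0$); a path whose horizon ends before the APO crossing
  returns a decision flagged `truncated`.
* **Path simulation.**  Poisson paths are built from cumulative exponential
  gaps rather than sorted uniforms: with tens of thousands of events the
  finite granularity of uniform variates can produce tied order statistics,
  while cumulative sums are strictly increasing by construction.

## What the generators emulate — and what they do not

`gen_censored_exponential()` draws exponential lifetimes with *independent
exponential* censoring whose rate $\lambda q/(1-q)$ is calibrated so the
expected censoring fraction is $q$.  This is the standard mechanism for
random right censoring, but real studies often censor administratively (a
fixed end of follow-up), which induces dependence between calendar time and
censoring that the generator does not emulate.  Likewise all lifetimes are
taken exchangeable with a constant hazard; passing tests therefore show
correctness of the estimators *under the exponential model*, not robustness
to non-constant hazards or informative censoring.  The Monte-Carlo harness
(`mse_study()`, `run_benchmark()`) spawns one sub-seed per replicate from
the root seed, so enlarging `reps` extends a study without reshuffling
earlier replicates.

Default study sizes are chosen to make Monte-Carlo error small relative to
the effects measured while keeping a full run at desk scale: shrinkage
MSE checks use $10^5$ replicates (standard errors well below 1% of the
quantities compared), the prior-averaged censored-survival comparison uses
$n = 30$ lifetimes and $10^4$ replicates, and the APO asymptote uses 100–200
paths observed to $t = 10^4$.  Acceptance bands are 3 Monte-Carlo standard
errors throughout.

## Known limitations

* The invariant-form results assume $\mu > 0$ (finite positive coefficient
  of variation); estimators for $\mu < 0$ would need the sign tracked
  separately.
* The exact invariant risk of $z_5\bar a^2$ for $\theta^2$ does not exist
  for $a z_5 > 0$; only the truncated risk and its optimum are provided,
  and results are flagged as truncated.
* `linexp` fits are intercept-only: covariates belong in a regression
  model (e.g. parametric survival regression), not in this conjugate
  analysis.
* Second-order optimality diagnostics for the APO rule (beyond the total
  Bayes risk and its standard error) are not implemented; the harness
  reports Monte-Carlo Bayes risk instead.

## A worked example

```{r example}
d <- data.frame(time = c(2, 3, 5), status = c(1, 1, 0))
fit <- linexp(survival::Surv(time, status) ~ 1, data = d,
              method = "bayes", prior = c(1, 1), a = 1)
summary(fit)
coef(fit)                 # (k/a) log(1 + a/r) on the Gamma(3, 11) posterior
predict(fit, times = c(1, 5, 10))
```
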