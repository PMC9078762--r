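Package: linexbayes
Title: Bayes, Shrinkage and Sequential Estimation under LINEX Loss
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimation of scale-type parameters under the asymmetric
    linear-exponential (LINEX) loss. Provides closed-form Bayes
    estimators from gamma posteriors with a quadrature oracle for
    verification; maximum-likelihood and Bayes-LINEX fitting of
    right-censored exponential lifetimes with survival and hazard
    curves; minimum-risk shrinkage estimators of the normal mean, of
    its square and of the variance, and of the negative-exponential
    scale and its square, under mean squared error and invariant LINEX
    risk; the asymptotically pointwise optimal (APO) stopping rule for
    the intensity of a homogeneous Poisson process under a gamma prior
    with linear sampling cost; and a seeded Monte-Carlo benchmark
    harness that compares estimators by bias, mean squared error and
    LINEX risk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
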