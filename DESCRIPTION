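Package: liabilityMetrics
Title: Analytic Evaluation of Genetic Risk Prediction Models Under the
    Liability Threshold Model
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates the predictive performance of genetic (or other)
    risk models analytically from two quantities: the overall disease
    probability K and the proportion of liability variance explained by
    measured risk factors (Vm). Under the liability threshold model the
    package computes the distribution of predicted absolute risks, the
    ROC curve and exact or binormal-approximate AUC, the predictiveness
    curve, the proportion of cases occurring in the top risk strata, the
    variance of predicted risks and the discrimination slope, the net
    reclassification improvement (NRI) over arbitrary risk categories via
    bivariate-normal conditioning, and the integrated discrimination
    improvement (IDI). Variant panels (allele frequencies and per-allele
    odds ratios) can be converted to genotype risks and total variance
    explained, and a seeded Monte-Carlo cohort simulator under a
    multiplicative odds-ratio model provides empirical counterparts of
    every analytic index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
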