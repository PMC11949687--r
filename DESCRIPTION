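Package: pdmbma
Title: Model-Based Meta-Analysis of Aggregate Pharmacodynamic
    Time-Course Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based meta-analysis (MBMA) of arm-level longitudinal
    efficacy summaries pooled from published trials, motivated by
    calcimimetic therapy (cinacalcet) of secondary hyperparathyroidism.
    Provides hyperbolic (Emax/ET50) and asymptotic-exponential onset
    models for biomarker decrease from baseline, hierarchical estimation
    with study-level random effects by maximum marginal likelihood
    (Laplace approximation or adaptive Gauss-Hermite quadrature),
    stepwise covariate selection, study-level nonparametric bootstrap,
    visual predictive checks, leave-one-out sensitivity analysis,
    median-split subgroup analysis, external dose-range comparison, and
    a synthetic literature generator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
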