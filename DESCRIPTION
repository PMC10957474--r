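Package: lnmdyn
Title: Longitudinal Compositional Microbiome Analysis with Bayesian
    Logistic-Normal Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models longitudinal gut-microbiome relative-abundance profiles
    from immunotherapy cohorts with a Bayesian multivariate logistic-normal
    linear model fitted in additive log-ratio coordinates via its conjugate
    matrix-normal inverse-Wishart posterior. Provides prevalence filtering and
    parsing of MetaPhlAn-style merged abundance tables, log-ratio geometry
    (alr/clr, multiplicative zero replacement), interaction design matrices
    with weighted-sum coding, post hoc marginal-mean contrasts with
    Bayesian-confidence-level significance and longitudinal dynamics
    classification, geometric-mean balance biomarkers with repeated
    cross-validated AUC, Kaplan-Meier and Cox survival analysis, and a
    synthetic cohort generator for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
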