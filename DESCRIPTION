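Package: intermaihda
Title: Intersectional MAIHDA for Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intersectional multilevel analysis of individual
    heterogeneity and discriminatory accuracy (MAIHDA) with a binary outcome:
    construction of intersectional strata from categorical survey dimensions,
    maximum-likelihood estimation of random-intercept logistic models by
    adaptive Gauss-Hermite quadrature, latent-scale variance partition
    coefficients, proportional change in variance, stratum-level
    discriminatory accuracy (AUC), empirical-Bayes stratum predictions with an
    additive/interaction decomposition, and a seeded synthetic-cohort
    generator emulating a Brazilian digital-exclusion survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
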