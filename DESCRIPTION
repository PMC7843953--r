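Package: twinace
Title: Twin ACE Liability-Threshold Models and Phenotypic Association
    Analysis for Obsessive-Compulsive Symptoms and Suicidality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between obsessive-compulsive
    symptoms (OCS) and suicidality in population twin cohorts. Provides a
    synthetic twin-cohort generator driven by a liability ACE model, a
    phenotypic layer (log-transform standardisation, tetrachoric
    correlation and its principal component analysis, composite outcome
    coding, and cluster-robust logistic regression for twin data), and a
    biometric layer implementing univariate, bivariate correlated-factors
    and trivariate Cholesky ACE liability-threshold models estimated by
    raw-data full-information maximum likelihood, with profile likelihood
    confidence intervals, model comparison by -2LL and AIC, and
    decomposition of phenotypic correlations into genetic and
    environmental shares. A pipeline orchestrates the full analysis
    sequence and emits regression and decomposition tables.
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
    Matrix,
    mvtnorm,
    purrr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    numDeriv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
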