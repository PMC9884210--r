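Package: hcybn
Title: Bayesian-Network Risk-Factor Analysis for Hyperhomocysteinemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for categorical risk-factor
    epidemiology of hyperhomocysteinemia (serum homocysteine > 15 umol/L):
    clinical variable coding with guideline cut-offs, chi-square screening of
    candidate factors, stepwise binary logistic regression, score-based
    discrete Bayesian-network structure learning by tabu search and hill
    climbing under the BIC, maximum-likelihood estimation of conditional
    probability tables, exact inference by variable elimination for
    sequential risk reasoning, and ROC/AUC model comparison with DeLong
    confidence intervals. Includes a calibrated synthetic-population
    generator with known ground-truth structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
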