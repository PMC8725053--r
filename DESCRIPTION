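Package: carelessboost
Title: Detecting Careless Responding in Likert Surveys with Boosted Trees
    and Person-Fit Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for flagging careless respondents in Likert-type survey
    data. Implements the traditional data-driven detection indices
    (Mahalanobis distance, psychometric antonyms, even-odd consistency,
    longstring, intraindividual response variability), a polytomous-IRT
    person-fit statistic (Zh) based on per-construct graded response models,
    and a from-scratch stochastic gradient-boosted-tree classifier with
    logistic loss, up-sampling, and cross-validated grid search. Includes a
    Gaussian-copula ordinal-response simulator with three careless-response
    styles and response-time paradata, plus a replication harness that
    benchmarks all detectors on simulated test samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
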