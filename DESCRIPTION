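Package: multicf
Title: Multi-Objective Counterfactual Recommendations for Disease Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates Pareto-optimal counterfactual feature recommendations
    that simultaneously reduce the predicted probabilities of several diseases.
    Black-box per-disease risk models trained on overlapping tabular feature
    sets are optimised jointly over the unioned, constraint-restricted feature
    space with an elitist non-dominated-sorting genetic algorithm (NSGA-II)
    supporting mixed continuous, binary and categorical genes, feature
    immutability and user value windows. Final Pareto fronts are ranked with a
    weighted-sum-plus-positive-gap penalty. Includes a risk-model training
    pipeline (median imputation, one-hot encoding, ROC-AUC model selection), a
    synthetic multi-disease problem generator with analytic optima and Pareto
    fronts for validation, and a command-line interface.
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
    optparse,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
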