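Package: banditrl
Title: Reward Learning, Model Fitting and Test-Retest Reliability for a
    Drifting Two-Armed Bandit Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a gamified two-option reward-learning task whose win
    probabilities follow a bounded Gaussian random walk, fits a four-parameter
    reinforcement-learning model (valence-specific learning rates, reward
    sensitivity, and an additive probability-magnitude weighting) to per-run
    choices by multi-start constrained maximum likelihood, derives a
    simulation-based quality-control threshold for random responding, maps
    expected task performance across the parameter space, and quantifies
    longitudinal psychometrics (intraclass correlations, leave-run-out
    test-retest curves, practice-trend mixed models) on synthetic cohorts
    with designed between- and within-participant variance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    jsonlite,
    rlang,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lmerTest,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
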