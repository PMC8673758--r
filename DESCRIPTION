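Package: creditassign
Title: Simulation and Model-Based Analysis of Credit Assignment in a
    Three-Option Restless Bandit Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a three-option probabilistic reversal-learning
    (restless bandit) task with drifting, weakly correlated reward
    schedules, and implements a reinforcement-learning model of choice in
    which a global reward state and outcome-independent choice-memory
    traces (stimulus and location) modulate value learning and the
    decision value.  Provides hierarchical empirical-Bayes (iterative
    maximum a posteriori) model fitting with bound-respecting link
    functions, occasion-lagged win-stay/lose-shift regressions,
    credit-assignment matrices, mixed-effects condition contrasts,
    construction of hemodynamic design-matrix regressors, and
    synthetic-cohort experiments for parameter recovery and detection of
    injected condition effects such as a stimulation-induced reduction in
    learning rate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
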