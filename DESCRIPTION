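Package: dexrl
Title: Offline Reinforcement Learning for Dexmedetomidine Dosing to Prevent ICU Delirium
Version: 0.1.0
Authors@R: person("Dana", "Kim", email = "dana.kim@example.org", role = c("aut", "cre"))
Description: Tools for learning and evaluating 6-hourly dexmedetomidine dosing
    policies aimed at preventing delirium in intensive-care patients. Provides
    a synthetic electronic-health-record trajectory simulator with a
    Monte-Carlo ground-truth oracle, preprocessing of irregular bedside
    records into a complete 6-hourly Markov decision process (median binning,
    plausibility-bound outlier removal, time-weighted and chained-equation
    imputation, 0.1 mcg/kg/h dose discretization, terminal reward assignment),
    conservative Q-learning with Double-DQN temporal-difference targets,
    off-policy evaluation by fitted-Q evaluation and weighted importance
    sampling with effective-sample-size diagnostics and bootstrap confidence
    bounds, gradient-boosted surrogate models with Shapley-value feature
    attributions (including PCA-based component attributions), and cohort
    descriptive statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    nnet,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
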