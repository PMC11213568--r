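Package: infolearn
Title: Information Dynamics of Reward and Punishment Learning Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Model-based information-theoretic analysis of reward and
    punishment learning in trial-locked neural power signals. Fits a
    Q-learning model (learning rate, softmax temperature, perseveration)
    to choices from a probabilistic instrumental learning task, extracts
    trial-wise reward and punishment prediction errors, and quantifies
    their neural encoding with Gaussian-copula mutual information,
    redundancy/synergy via interaction information, and directed flow via
    delay-averaged transfer entropy, with random-effects cluster-based
    permutation statistics at the group level. A synthetic-data module
    generates the task, agent behavior, and gamma-power epochs with
    controlled redundant, synergistic, and lagged-directed coupling so
    every estimator can be validated against ground truth.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
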