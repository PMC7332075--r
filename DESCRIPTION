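Package: twostepRL
Title: Model-Free and Model-Sensitive Reinforcement Learning in the Two-Stage Decision Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical model fitting for the two-stage
    (two-step) Markov decision task. Provides a generative task engine
    (probabilistic common/rare transitions, dwell-then-redraw outcome levels,
    drifting juice magnitudes, forced trials), a family of trial-by-trial
    reinforcement-learning agents (SARSA, Q-learning, three transition-model
    learners, the Hybrid mixture and the Hybrid+ model with outcome-dependent
    one-trial choice boosts), fixed-effects maximum-likelihood and
    mixed-effects empirical-Bayes EM fitting with Laplace posteriors,
    model comparison (BIC, integrated BIC via prior sampling, protected
    exceedance probability, likelihood-ratio tests), and descriptive
    behavioural analyses (stay-probability tables, lagged logistic choice
    regression, reaction-time preprocessing and regression, exponential decay
    fits). Includes surrogate-data generation and parameter/model recovery
    harnesses plus a glossary-driven reader for deposited per-trial datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    metafor
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    yaml
Config/testthat/edition: 3
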