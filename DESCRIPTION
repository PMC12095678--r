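Package: hbrl
Title: Hierarchical Bayesian Reinforcement Learning for Probabilistic
    Reward and Punishment Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and hierarchical Bayesian analysis of two-choice
    probabilistic instrumental learning tasks with interleaved reward,
    punishment and neutral trials, as used in pharmacological studies of
    serotonergic modulation of learning. Provides a task-schedule
    generator and cohort simulator, trial-level likelihoods for four
    reinforcement-learning models (Rescorla-Wagner variants with
    reinforcement sensitivity and stimulus stickiness, and an
    experience-weighted attraction model), adaptive MCMC estimation of
    hierarchical group models with non-centred subject effects,
    highest-density-interval summaries of group mean differences,
    bridge-sampling estimates of marginal likelihoods for model
    comparison, and the classical behavioural statistics layer
    (repeated-measures ANCOVA, Welch t, Cohen's d, chi-squared with phi,
    Benjamini-Hochberg correction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
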