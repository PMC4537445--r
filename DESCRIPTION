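Package: pvdrl
Title: Reinforcement Learning Models of Probabilistic Discrimination and
    Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of two-choice probabilistic
    visual discrimination and reversal learning of the kind used in primate
    lesion studies of serotonin function. Provides a synthetic-data
    generator for the task (probabilistic reward/punishment feedback,
    session-level learning criterion, reversals), an eight-member family
    of softmax delta-rule reinforcement-learning models with stimulus and
    side stickiness, maximum a posteriori and hierarchical Bayesian
    parameter estimation with highest-density-interval summaries, model
    comparison by BIC and AICc, model-free behavioural measures (errors
    to criterion, win-stay/lose-shift analysis split by feedback
    veracity), virtual-subject necessity/sufficiency experiments, and a
    discrete-event simulator of a concurrent variable-interval
    reward/punishment schedule with response-suppression metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
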