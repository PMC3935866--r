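Package: tdarousal
Title: Temporal-Difference Simulation of Probabilistic Reward Extinction
    with Arousal-Gated Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates classical conditioning with probabilistic rewards
    using a temporal-difference (TD(lambda)) learner with separate positive
    and negative association weights, a complete serial compound stimulus
    representation, break-only forgetting, and a slowly decaying arousal
    signal that gates the learning rate during extinction.  Provides
    builders for trial-constant and reward-constant reward schedules,
    multi-phase acquisition/extinction/break protocols, simulated
    pharmacological modulation of the prediction error, parameter sweeps
    over reward probability, arousal persistence and training length, and
    classification of extinction-rate curves (partial reinforcement
    extinction effect, inverted-U, monotone shapes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
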