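Package: trajlearn
Title: Reward-Based Trajectory Learning and Bayesian Credit Assignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and model fitting for reinforcement motor learning of
    two-parameter reach trajectories under weighted scalar rewards. Provides
    the (direction, curvature) trajectory family and its least-squares
    inversion, weighted composite reward functions with monetary scaling, a
    grid-based Bayesian learner with memory decay and reward-prediction-error
    updates, synthetic cohort generation matching the study protocol (2 reward
    conditions x 8 participants x 50 targets x 25 trials), a 4-parameter model
    fitter scored by variance explained in trial-to-trial trajectory
    decisions, and learning-curve analyses (exponential fits, quiver
    summaries, session-wise meta-learning tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
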