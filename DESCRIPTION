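Package: coursetrace
Title: Sequence Analysis and Bayesian Modelling of Task-Completion Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ordered task-completion sequences from online
    courses. Provides ensemble descriptive statistics (position and transition
    matrices at task and session resolution, group contrasts, Jensen-Shannon
    distance profiles, per-learner deviation heat-map matrices), task-centric
    group comparisons and a student confidence score, a reduced hypercubic
    Bayesian generative model for task acquisition with exact likelihood and
    Metropolis MCMC inference, a posterior-odds classifier that predicts group
    membership from sequence prefixes, and a seeded synthetic cohort generator
    for end-to-end testing without access to private learning-records data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
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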