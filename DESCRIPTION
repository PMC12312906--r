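Package: locolearn
Title: Hierarchical Bayesian State-Space Modeling of Locomotor Skill Learning
Version: 0.1.0
Authors@R:
    person("locolearn", "developers", email = "locolearn@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing trial-by-trial locomotor skill learning in
    obstacle-negotiation tasks with two interleaved obstacle heights. Provides
    a dual-context linear state-space model of foot clearance with a dead-zone
    (success-range) error signal, a learning rate and a contextual-interference
    parameter; a three-level hierarchical Bayesian estimator (adaptive
    Metropolis-within-Gibbs, Student-t observation noise) with split and
    rank-normalized R-hat convergence diagnostics and WAIC model comparison;
    Bayesian hypothesis tests (probability of direction on trimmed posterior
    differences, ROPE on standardized effect sizes); behavioral performance
    metrics (performance error, online improvement, overnight retention) and
    their association regressions; and a synthetic-cohort generator with known
    ground truth so the full pipeline is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
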