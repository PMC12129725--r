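Package: banditrl
Title: Hierarchical Reinforcement Learning Models of Four-Armed Bandit
    Behaviour with Brain-Network Centrality Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits five reinforcement-learning models of reward and
    punishment decision-making in a four-armed bandit task by hierarchical
    Bayesian inference (Hamiltonian Monte Carlo with analytic gradients),
    compares them by Pareto-smoothed importance-sampling leave-one-out
    cross-validation (PSIS-LOO), and contrasts group-level parameters with
    posterior highest-density intervals. A companion connectivity stage
    builds binarized correlation networks from parcellated time series,
    computes five nodal centrality measures, and screens centrality against
    clinical scores with default Bayes-factor correlations corrected by a
    Bayesian false-discovery-rate procedure. A synthetic-data module
    generates task schedules, simulated cohorts, parcel time series and
    clinical scores with known ground truth for recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
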