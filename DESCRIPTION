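Package: stategames
Title: Cooperation in Two-State Stochastic Games with and without
    Environmental Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of cooperation in two-player,
    two-state stochastic games played with memory-one strategies. Computes
    exact stationary outcome distributions, payoffs and cooperation rates for
    strategy pairs (with or without implementation errors and discounting),
    evolutionary dynamics under the pairwise comparison process in the
    rare-mutation limit (fixation probabilities, embedded strategy-level
    Markov chains, invariant distributions, invasion graphs, trajectory
    simulation), equilibrium analysis of memory-one strategies (Nash checks
    by enumeration and subgame perfection by dynamic programming), and a
    systematic classification of environmental transition vectors by their
    value of state information, including the weak-selection proxy rule and
    symmetry reduction of the deterministic game space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
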