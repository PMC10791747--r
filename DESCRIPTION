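Package: triguild
Title: Adaptive Rewiring Dynamics of Three-Guild Plant-Pollinator-Herbivore Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for multiplex ecological networks in which a plant guild
    links a mutualistic (pollinator) and an antagonistic (herbivore) sub-network.
    Communities are assembled from Gaussian niche overlap on a one-dimensional
    niche axis, their dynamics follow a Lotka-Volterra model with type II
    functional responses, and animals adaptively rewire their plant partners,
    accepting a switch only when it raises their own equilibrium biomass.
    Includes local-stability (resilience) analysis via the analytic Jacobian,
    NODF nestedness and Barber bipartite modularity with null-model z-scores,
    per-plant degree-centrality and energy-budget statistics, and orchestration
    of interaction-strength sweeps, asymmetric sub-network scenarios and Latin
    hypercube sensitivity designs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    purrr,
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
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
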