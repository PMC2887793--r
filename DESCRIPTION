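Package: netsync
Title: Inferring Physical Network Connectivity from Synchronization Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates noisy Kuramoto phase oscillators on undirected
    substrate networks spanning regular to scale-free topologies, quantifies
    synchronization through global and local order parameters and pairwise
    phase coherence (PPC), assembles weighted networks of synchronization
    (WNS), locates the synchronization transition by finite-size scaling, and
    reconstructs the physical network from thresholded PPC with ROC/AUC
    evaluation.  The stochastic Heun integrator for the coupled oscillator
    dynamics is implemented in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
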