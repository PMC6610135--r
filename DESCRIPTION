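Package: cpgnet
Title: Network Simulation and Two-Timescale Correlation Analysis for
    Central Pattern Generator Architecture Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers whether the common drive behind rhythmic motor activity
    comes from a dense/divergent or a sparse/convergent premotor network,
    from the correlation structure of pairwise neural recordings. Provides
    fixed in-degree bipartite topologies with a sparseness calculus, a
    conductance-based leaky integrate-and-fire network simulator with
    rhythmic inhomogeneous-Poisson drive and feedforward/recurrent
    inhibition motifs, slow/fast membrane-potential decomposition with
    sliding correlograms and circular-shift shuffle nulls, kernel
    spike-rate correlation matrices with Rayleigh rhythmicity screening and
    Hilbert-phase polar histograms, spike-triggered-median connectivity
    probing with interval-jitter surrogates and IPSP decay fitting, and
    ground-truth-labelled synthetic generators for validating every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
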