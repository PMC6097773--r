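Package: tvconnsim
Title: Simulation Benchmark for Time-Varying EEG Source Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end simulation framework for benchmarking time-varying
    directed connectivity estimation from distributed EEG sources. Generates
    multi-trial source signals from a ground-truth time-varying multivariate
    autoregressive (MVAR) network modelling the visual spatial attention
    system, propagates them to scalp electrodes through an analytic
    three-shell spherical head model, reconstructs cortical sources with
    sLORETA, extracts region-of-interest time series via competing
    dipole-selection strategies, tracks the MVAR coefficients with classical
    and general linear Kalman filters, computes squared partial directed
    coherence (PDC), and scores every combination against the known ground
    truth over a signal-to-noise by trial-count factorial design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
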