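Package: sptkinetics
Title: Single-Particle-Tracking Kinetics of Membrane Receptor Dimerization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of two-color single-particle-tracking (SPT)
    and immunogold point-pattern data for membrane receptor interaction
    studies. Provides time-lag-averaged mean squared displacement (MSD)
    curves and diffusion-coefficient fits, correlated-motion analysis of
    candidate two-color particle pairs, a two-state (free/dimer) hidden
    Markov model over pair-separation series with dissociation-rate
    (k_off) estimation and bootstrap uncertainty, and bivariate Ripley's
    K co-clustering statistics with Monte-Carlo confidence envelopes.
    Includes a stochastic trajectory and point-pattern simulator with
    known ground truth so every stage of the pipeline is testable without
    raw microscopy data. All user-facing functions take and return data
    frames and compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
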