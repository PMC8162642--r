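Package: txcycle
Title: Single-Cell Transcription-Cycle Inference from Dual-Color Nascent RNA Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers effective transcription-cycle parameters (initiation rate,
    elongation rate, nascent-transcript cleavage time, onset time, channel
    calibration and basal fluorescence) for single cells from paired 5' MS2 /
    3' PP7 nascent-RNA fluorescence time series.  Provides the deterministic
    forward model mapping parameters to predicted two-channel traces, per-cell
    Bayesian estimation by adaptive Metropolis MCMC with chain diagnostics,
    automated curation of fits including a transcriptional-bursting flag,
    synthetic-trace and stochastic RNA-polymerase stepping (exclusion-process)
    simulators, and downstream statistics: calibration-factor fitting,
    two-color correlated/uncorrelated noise decomposition, bootstrapped
    coefficients of variation, rank correlations with posterior propagation,
    transcript density and polymerase occupancy, and binning along the
    embryo's anterior-posterior axis.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
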