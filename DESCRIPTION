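Package: sckinetics
Title: Aggregated Markov Kinetic Analysis of Single-Channel Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Kinetic analysis of single ion-channel dwell sequences with
    aggregated continuous-time Markov models. Provides Q-matrix machinery
    (generator construction, equilibrium occupancies, spectral dwell-time
    densities, derived equilibrium constants), exact stochastic simulation of
    gating schemes with dead-time censoring, burst definition via a critical
    closed duration, exponential-mixture dwell-time fitting, missed-event
    corrected maximum-likelihood estimation of rate constants with standard
    errors across multiple recordings and ligand concentrations, open-channel
    block concentration-series analysis, and binomial electrical
    fingerprinting of subunit stoichiometry from single-channel amplitude
    classes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
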