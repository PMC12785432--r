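Package: gabakin
Title: Kinetic Modeling and Single-Channel Analysis of GABA-A Receptor Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregated Markov modeling of ligand-gated ion channel gating,
    built around the alpha1-beta2-gamma2 GABA-A receptor. Simulates macroscopic
    open-probability responses to agonist concentration pulses by spectral
    relaxation of the Q-matrix and extracts the standard kinetic descriptors
    (10-90% rise time, biexponential desensitization, fraction remaining,
    single-exponential deactivation, log-logistic EC50), runs systematic
    rate-constant perturbation scans, synthesizes stochastic single-channel
    event sequences with finite recording resolution and cluster structure,
    analyzes dwell-time distributions by left-truncated exponential-mixture
    maximum likelihood, and estimates gating rate constants from
    resolution-limited event lists by missed-event-corrected
    (Hawkes-Jalali-Colquhoun) maximum likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    car,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
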