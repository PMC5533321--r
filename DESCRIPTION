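Package: ewdyn
Title: Early-Warning Signals in Perturbed Models of Synchronization and
    Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates two perturbed dynamical systems that undergo critical
    transitions -- the mean-field Kuramoto oscillator ensemble with white
    frequency noise, and a cylindrical cellular automaton of atrial tissue
    with stochastic conduction failure and variable pacing -- and computes
    early-warning indicators of the transition: ensemble statistical
    moments, lag-1 autocorrelation, Welch power spectra with power-law
    diagnostics, and critical-point estimation with alignment across
    perturbation levels.  Pacing schedules include fixed, uniform and
    Gaussian pulse-to-pulse intervals, plain-text RR-interval files, and a
    synthetic 1/f-correlated RR surrogate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
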