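Package: ecoscape
Title: Energy Landscapes, Transition Paths and Early Warnings for
    Mutualistic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse stochastic transition dynamics in bipartite
    plant-pollinator networks governed by generalized Lotka-Volterra
    dynamics with saturating (Holling type II) mutualism. The package
    detects multistability (including intermediate states with few
    surviving pollinators), quantifies the quasi-potential energy
    landscape via a truncated moment-equation (Gaussian mixture)
    approximation of the Fokker-Planck stationary density, projects it
    onto interpretable plant/pollinator principal-component coordinates,
    computes Freidlin-Wentzell minimum-action transition paths with
    non-negativity constraints, simulates Langevin dynamics with white
    and colored noise (mean first passage times, ramped-parameter
    collapse and recovery, hysteresis thresholds), and evaluates the
    landscape barrier height as an early-warning signal of collapse
    against trajectory-based metrics (AR(1), variance, CV, Fano factor)
    using a BDS nonlinearity test. A closed-form analysis of the
    two-dimensional mean-field reduction and a one-at-a-time global
    sensitivity analysis of transition actions are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
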