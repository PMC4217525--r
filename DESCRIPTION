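Package: camnoise
Title: Stochastic Calcium Noise in Buffered Microdomains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of stochastic free-calcium fluctuations
    in femtoliter microdomains containing calcium buffers. Provides four
    consistent trajectory engines (exact Gillespie stochastic simulation,
    chemical Langevin equation, its excess-buffer-approximation reduction,
    and an Ornstein-Uhlenbeck surrogate), closed-form calculators for the
    stationary noise parameters (mean, autocorrelation time, volatility),
    trajectory statistics including autocorrelation-time and relaxation-time
    estimators, a chemical-master-equation stationary oracle for small
    systems, and a colored-noise-driven double-well system illustrating
    noise-color-dependent coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
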