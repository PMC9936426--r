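Package: chondronet
Title: Network-Based Modelling of Mechano-Inflammatory Chondrocyte Regulation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Continuous (semi-quantitative logic) simulation of signed
    directed regulatory networks describing chondrocyte mechanotransduction
    and inflammation. Provides a normalized-input ordinary differential
    equation engine with fixed-step fourth-order Runge-Kutta integration,
    clamped stimuli, and a state-dependent integrin conformational switch
    driven by RGD peptides; built-in mechano-inflammatory stimulation
    scenarios; full-factorial perturbation designs with balanced ANOVA
    variance decomposition (Pareto importance, effect signs, marginal
    means); a literature-derived qualitative validation harness; analytic
    motif and random-network fixtures; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
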