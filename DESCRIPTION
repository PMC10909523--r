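Package: oxysim
Title: Spiking, Secretion and Plasma Modelling of Oxytocin Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of magnocellular oxytocin neurons as
    modified integrate-and-fire units with spike-triggered afterpotentials
    (HAP, fast DAP, medium AHP) under random synaptic input; spike-pattern
    statistics (interspike-interval histogram, hazard function, index of
    dispersion, binned firing rates and constrained ramp fits); genetic
    algorithm fitting of model variants to pattern summaries and
    construction of consensus parameter sets; and a stimulus-secretion
    coupling model with activity-dependent facilitation feeding a linear
    two-compartment plasma pharmacokinetic model, used to predict plasma
    oxytocin concentrations in response to a gavage feeding protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
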