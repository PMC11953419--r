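Package: pecircuit
Title: Hierarchical Prediction-Error Circuits for Uncertainty Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rate-based simulation of cortical prediction-error (PE)
    microcircuits that estimate the mean and variance of their inputs.
    The package builds 8-unit mean-field circuits of negative and positive
    PE neurons (two-compartment pyramidal cells) with PV, SOM and VIP
    interneurons, composes them into a two-level hierarchy with memory
    (mean) and variance neurons, and computes the uncertainty-weighted
    integration of sensory inputs and predictions. Includes seeded
    piecewise-constant stimulus protocols, neuromodulatory perturbation
    experiments, and contraction-bias analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
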