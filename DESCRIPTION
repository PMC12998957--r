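Package: einet
Title: Probabilistic Excitation-Inhibition Balance in Feedforward
    Inhibitory Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling how excitatory and inhibitory inputs
    combine in feedforward inhibitory circuits. Provides the probability
    algebra of excitatory-inhibitory cancellation (net drive, effective
    inhibitory probability, mean synaptic currents, conductance
    correction), an event-level leaky integrate-and-fire simulator with
    alpha-function synapses and Poisson barrages, analytic input-output
    theory for sustained stimuli (oscillatory and fluctuation-driven
    firing regimes), a first-spike probability predictor for brief
    stimuli, and protocol runners for input-output curves, gain
    modulation of tuned responses, and temporal firing profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
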