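Package: replaynet
Title: Up/Down State Dynamics in Spiking Networks with Phase-Coded Attractors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates noisy leaky integrate-and-fire networks whose synaptic
    matrix stores phase-coded spatiotemporal spike patterns through a balanced
    spike-timing-dependent plasticity kernel followed by competitive pruning.
    Provides the companion analysis stack: population rate binning, dynamical
    regime classification (exponential, bimodal, Gaussian), neuronal avalanche
    detection with power-law size and duration fits, inter-avalanche waiting
    time distributions under linear and logarithmic measures, up/down state
    segmentation, pattern replay scoring, and an optional short-term synaptic
    depression variant of the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
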