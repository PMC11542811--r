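Package: plastenergy
Title: Metabolic Cost Accounting for Synaptic Plasticity in Neural Network Learning
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates single-hidden-layer perceptrons trained by per-sample
    stochastic gradient descent while accounting for the metabolic energy of
    every synaptic weight change under the M_alpha family of cost measures
    (M0 counts non-zero updates, M1 accumulates absolute weight change).
    Implements energy-saving plasticity restriction strategies -- dropconnect,
    fixed Bernoulli synapse masks, fixed hidden-neuron masks, coordinated
    plastic subnetworks, and competitive top-k update selection -- together
    with two-compartment synaptic caching (transient/persistent weights with
    threshold consolidation). Provides the analytic counting theory for
    optimal mask densities, power-law scaling fits, the inverse Simpson
    update-diversity index, and extrapolation of training cost to
    cortex-scale synapse counts. Includes an IDX (MNIST-format) reader and a
    synthetic dataset generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
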