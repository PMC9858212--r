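Package: nisr
Title: Neural Information Squeezer for Detecting Causal Emergence in Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns continuous coarse-graining maps and macro-level dynamics
    from micro-level time series using an invertible neural network (affine
    coupling flow) composed with a projection, trains the resulting
    encoder-dynamics-decoder by likelihood maximisation, and scans the macro
    dimension q for the scale at which dimension-averaged effective
    information peaks (causal emergence). Ships deterministic simulators for
    three benchmark systems (a noisy two-sensor spring oscillator, an
    8-state Markov chain, and a 4-node probabilistic Boolean network),
    effective-information and mutual-information estimators, and a
    command-line interface for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
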