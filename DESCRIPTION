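Package: wireopt
Title: Anchored Wiring-Length Minimization for Spatial Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the wiring economy of spatial neural networks
    such as the C. elegans connectome. Given neuron positions partitioned into
    anchored (motor/sensory) and free (interneuron) cells and a weighted
    chemical/electrical connection graph, the package minimizes the total
    wiring length over the free positions under l1, Euclidean, squared
    Euclidean and higher-power Euclidean connection costs, compares optimal,
    real and random layouts via Monte-Carlo null models, sweeps connection
    weighting schemes, detects displacement outliers, and generates synthetic
    worm-like connectomes (including planted-optimum instances) so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
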