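Package: connergy
Title: Energy-Constrained Generative Models of Brain Network Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the formation of brain-like weighted networks by
    minimizing a normalized energy function, the per-node ratio of an
    activity (signal-transfer) cost to a wiring cost, under boundedness
    constraints: an upper limit on connection strength and a homeostatic
    lower limit on network activity. Training uses stochastic gradient
    descent with the Adam optimizer on random spin-like input signals.
    Includes the network statistics used to compare trained models with
    real connectomes: inter-run stability RMSE on ordered weights,
    cumulative node-strength distributions, and maximum-cluster-size
    curves over strength-thresholded subnetworks, plus readers for dense
    and edge-list connectivity matrices and a synthetic connectome
    generator for offline testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr, yaml
Config/testthat/edition: 3
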