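Package: netpert
Title: Perturbation Pattern Prediction on Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts how a sustained perturbation of one species in a
    biochemical reaction network propagates to the others. Implements the
    ground-truth sensitivity matrix from the Jacobian of a dynamical model
    at steady state, the topology-only predictors of the DYNAMO family
    (first-neighbor, distance, network propagation), a rank-based
    enhancement factor derived from the Jacobian, and a compact two-layer
    graph convolutional network that learns per-node impact labels across a
    corpus of networks so the enhancement can be predicted for models whose
    kinetics are unknown. Includes a generator of stable synthetic dynamical
    models, Spearman rank-correlation scoring of predictions against ground
    truth, and network-property/accuracy correlation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    deSolve,
    jsonlite,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
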