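Package: nlpnn
Title: Network-Limited Polynomial Neural Networks with Attention-Empowered
    Boosting for Imbalanced Clinical Tabular Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Binary classifiers for small clinical tabular datasets with
    hidden (nonlinear) features and skewed class ratios. Implements a
    network-limited polynomial neural network (NLPNN): polynomial feature
    layers are built greedily from training data by singular value
    decomposition and orthogonal least squares under explicit depth and
    per-layer width caps, and topped with an L2-regularized hinge-loss
    linear readout selected on a validation split. An attention-empowered
    variant (AEPNN) boosts NLPNN base learners with exponential-loss sample
    reweighting to recover recall on minority (sick) classes. Includes
    confusion-matrix metrics (accuracy, specificity, precision, recall, F1,
    G-mean, AUC), the CSV experimental protocol (zero-fill of missing
    values, stratified 8:2 splits), a seeded synthetic-data generator with
    polynomial decision boundaries and controllable imbalance, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
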