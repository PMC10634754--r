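Package: hyperMEG
Title: Hyperbolic Graph Embedding of MEG Functional Connectivity Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Embeds phase-locking-value (PLV) functional connectivity networks
    into low-dimensional hyperbolic (Poincare ball) space and analyses the
    hierarchical organisation of the embedded networks. Provides numerically
    safe Poincare-ball operations at arbitrary negative curvature (geodesic
    distance, origin exponential/logarithmic maps, Mobius addition and
    matrix-vector multiplication, and a differentiable Frechet mean), a
    two-layer hyperbolic graph convolutional network (HGCN) with Frechet-mean
    aggregation, learnable curvature and a Fermi-Dirac link decoder trained
    with a PLV-weighted mean squared error, together with a Euclidean GCN and
    a shallow Poincare embedding as baselines. Includes a link-prediction
    evaluation harness with subject-grouped cross-validation and mean average
    precision, a radius-based hierarchy metric with subnetwork aggregation,
    group classification and covariate-adjusted group-difference statistics,
    and seed-deterministic synthetic cohort generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    e1071,
    pROC
Suggests:
    testthat (>= 3.0.0),
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
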