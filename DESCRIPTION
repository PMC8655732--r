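Package: fmfs
Title: Federated Morphometry Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Federated sparse regression for surface-based morphometry.
    Implements a federated block coordinate descent solver for the group
    LASSO in which institutions exchange only aggregated gradient and Gram
    statistics (never row-level data), a federated safe-screening rule of
    the dual-polytope-projection family that provably discards inactive
    patch groups along a decreasing regularization path, and stability
    selection over the path to rank surface vertices by how often their
    radial-distance and tensor-based-morphometry features are selected.
    Includes a synthetic cohort generator with spatially smooth vertex
    features and planted predictive patches, frequency-map smoothing and
    ROI summarization, plain-text and packed-binary readers and writers,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
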