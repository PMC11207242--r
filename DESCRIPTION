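Package: fsff
Title: Frequency-Spatial Feature Fusion for Motor-Imagery EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-class motor-imagery EEG decoding with overlapping multi-scale
    filter-bank common spatial patterns (CSP), adaptive structural LASSO
    (AS-LASSO) feature selection, and a cross-validated classification
    harness. AS-LASSO is an adaptive LASSO whose per-feature penalty weights
    w_i = exp(-mu * s_i * e_i) fuse symmetric uncertainty between feature and
    class label (s_i) with eigenvalue-based CSP spatial information (e_i),
    solved by coordinate descent via the weight-rescaling reduction to plain
    LASSO. Includes an HDF5 epochs container, a seeded synthetic ERD-style
    EEG generator with ground truth for recovery testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    rhdf5,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    MASS,
    class,
    randomForest,
    rpart,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
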