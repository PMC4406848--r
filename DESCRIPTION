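Package: rprpca
Title: Robust Principal Component Pursuit with Random-Projection
    Preprocessing for Multi-Trial Spatio-Temporal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes stacked multi-trial or multi-perturbation
    spatio-temporal data matrices (trials by species-major time blocks)
    into a common low-rank response and a sparse aberrant response via
    Principal Component Pursuit, with an optional Kronecker-structured
    random-projection preprocessing step that de-sparsifies and
    de-eccentrifies the input to restore identifiability. Includes
    synthetic-data generators for sparse low-rank benchmarks, spike-rate
    trial tensors and perturbation-response time courses, plus downstream
    correlation-template event detection with ROC evaluation and
    correlation-distance hierarchical clustering on the disentangled
    components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
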