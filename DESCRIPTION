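Package: sdpc
Title: Sparse Deep Predictive Coding Models of the Early Visual System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a hierarchy of convolutional sparse-coding layers
    coupled by predictive-coding feedback, as a model of the early visual
    cortex (V1/V2). Provides non-negative ISTA/FISTA inference with a
    tunable feedback strength, Hebbian-style dictionary learning with atom
    renormalization, receptive-field back-projection (effective
    dictionaries), interaction-map (association-field) analysis built on
    circular statistics of fitted Gabor orientations, and a feedback
    denoising evaluation based on the structural similarity index. A
    synthetic-data module generates images from the model's own hierarchical
    generative process, contour stimuli, and noise-corrupted variants, so
    that every analysis can be exercised without external image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
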