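Package: spstack
Title: Cell-Type Deconvolution, Spatial-Domain Identification and Rigid
    3D Reconstruction for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis suite for multi-slice spatial transcriptomics.
    Deconvolutes spot-level cell-type proportions against a single-cell
    reference by training a variational autoencoder, a proportion
    predictor and a recovery head with maximum-mean-discrepancy domain
    adaptation on simulated pseudo-spots; identifies spatial domains
    jointly across slices with a Chebyshev-filter graph convolutional
    network and an adversarial slice discriminator; rigidly aligns
    consecutive slices (mirror, rotation, translation) by maximizing a
    domain-agreement objective with differential evolution; and models
    continuous 3D expression with Gaussian-process regression scored by
    a Bayes factor for spatial variability. Includes generators for
    pseudo-spots, synthetic references and perturbed 3D slice stacks,
    and the evaluation metrics used to benchmark each stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    methods
Config/testthat/edition: 3
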