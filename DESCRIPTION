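Package: miniscopr
Title: Source Extraction for Single-Photon Miniscope Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of single-photon miniature-microscope
    calcium imaging videos: vignetting, denoising and morphological
    background correction; rigid motion correction by recursive
    cross-correlation template matching; seed-based initialization with
    peak-to-noise and Kolmogorov-Smirnov refinement; constrained
    non-negative matrix factorization with per-pixel sparse spatial
    updates and autoregressive temporal deconvolution; unit merging and
    curation-label application; cross-session neuron registration; and a
    synthetic miniscope-video simulator with ground truth plus the
    matching and accuracy metrics needed to validate the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
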