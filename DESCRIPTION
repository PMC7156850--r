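Package: uqseg
Title: Quality Assessment of Voxel-Wise Uncertainty in Medical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to judge whether the voxel-wise uncertainty attached to a
    medical image segmentation is worth trusting. Builds reliability diagrams
    and expected/average calibration errors at dataset and subject level,
    measures how well thresholded uncertainty localizes segmentation errors
    (uncertainty-error Dice overlap and precision-recall AUC), and aggregates
    voxel-wise uncertainty into subject-level scores and feature panels
    (mean, boundary-masked, distance-weighted and volume-normalized
    weightings; shape, first-order and run-length features of the thresholded
    map) that feed a random-forest predictor of the Dice coefficient for
    segmentation failure detection. Ships a seeded synthetic brain-tumor-like
    cohort generator with controllable calibration (temperature), boundary
    uncertainty and failure modes (remote false-positive blobs, missed
    subregions, boundary jitter) so the full pipeline is testable without
    clinical data. Volumes are read and written as NIfTI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
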