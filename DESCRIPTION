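Package: flowmp
Title: Automated Detection, Counting and Shape Classification of
    Fluorescently Stained Microplastics in Flow-Cell Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantification of Nile-Red-stained microplastic
    particles recorded as fluorescence video in a flow cell. Bright particles
    are segmented per frame with a Canny-style edge-detection cascade inside a
    user-defined detection window, linked across frames so that each physical
    particle is counted exactly once, measured (feret diameters, circularity,
    aspect ratio, micrometre size and size category), cropped to 100x100
    images, and classified as grain or fiber by a small convolutional neural
    network trained with mirror and rotation augmentation. A synthetic
    flow-cell video simulator with exact ground truth supports end-to-end
    validation, and evaluation utilities compute per-class correct-answer
    rates, detection efficiency against ground truth, and size distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
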