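Package: sicklekin
Title: Automated Assessment of Transient Sickling Kinetics in Sickle Red
    Blood Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-vision pipeline for quantifying deoxygenation-induced
    sickling of sickle-cell-disease red blood cells in time-lapse microscopy.
    Provides a seeded synthetic image generator with ground truth, classical
    cell segmentation with diameter-based overlap exclusion, seven contour
    shape factors plus intensity skewness and kurtosis per cell, a 17-layer
    convolutional neural network for two-class (nonsickled/sickled) patch
    classification trained with Adam and categorical cross-entropy, and
    population-level sickled-fraction kinetics with per-cell sickling delay
    times under a timed oxygenation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
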