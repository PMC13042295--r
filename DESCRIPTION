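Package: rhizolapse
Title: Temporal Plant Phenotyping from Multi-Class Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for time-lapse plant phenotyping experiments that
    produce per-frame multi-class segmentation masks (background, main root,
    lateral roots, seed, hypocotyl, leaves, petiole). Provides temporal
    consistency smoothing of mask sequences, skeleton-graph reconstruction of
    root system architecture with main/lateral axis classification, a
    catalogue of architectural, angular and growth-rhythm traits, a
    multi-plant screening mode with Kalman/Hungarian seed tracking and Hill
    germination kinetics, functional principal component analysis of growth
    trajectories, and Root System Markup Language (RSML) interchange. A
    synthetic seedling renderer with exact ground truth makes every stage
    testable without camera data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    minpack.lm,
    xml2,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
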