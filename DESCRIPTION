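Package: pyrascreen
Title: Hierarchical Pyramid Screening of Whole-Slide Pathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-to-fine lesion screening for multiresolution pathology
    slides. Provides an image-pyramid data model with tissue masking and
    tiling, a quadtree location-code search that descends from coarse to
    fine levels while pruning benign regions, a small encoder-decoder
    density-regression network with an optional patch classifier head, an
    LSTM residual-count fusion layer for patch sequences, density-map cell
    detection with non-maximum suppression and point clustering, TNM-style
    slide staging into negative/ITC/micro/macro classes, segmentation and
    per-class accuracy metrics, and a fully labelled synthetic-slide
    generator so the whole pipeline can be trained and evaluated at desk
    scale on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
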