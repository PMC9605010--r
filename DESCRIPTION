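Package: trichoscan
Title: Hair Follicle Classification and Hair-Loss Severity Estimation from Scalp Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for trichoscopy (scalp microscopy) image analysis: reading and
    writing circular follicle annotations in the VGG Image Annotator (VIA) JSON
    dialect, a synthetic scalp-image simulator with exact ground truth, a classical
    reference follicle detector behind a pluggable detection contract, rule-based
    three-class follicle state classification (severe / normal / healthy) from
    measured follicle radius, hair count and hair thickness, local and scalp-level
    hair-loss severity indices with a 12-region heatmap, and a full detection and
    classification evaluation suite (circle IoU, average precision, mAP, confusion
    matrices, support-weighted misclassification rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
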