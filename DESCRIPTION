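Package: fundusiqa
Title: Fundus Image Quality Assessment with Local and Global Attention Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: No-reference quality assessment of retinal fundus photographs along
    human-visual-system dimensions (uneven illumination/color, blur, low
    contrast, overall). Implements a convolutional classifier that aggregates
    local multi-scale features -- rearranged by a spatial-information-retained
    (space-to-depth) scheme onto the coarsest feature grid -- with global
    features under spatial or self attention, trained with binary
    cross-entropy. Includes image canonicalization (blank-crop, 512x512
    resize, eye-area masking, Gaussian-noise corruption), stratified splits
    and cross-validation, ROC/AUC evaluation, attention/saliency heat maps,
    a synthetic fundus generator with programmable quality defects, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
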