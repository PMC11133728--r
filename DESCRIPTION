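Package: tradshm
Title: Tradescantia Stamen-Hair Bioassay Image Classification and
    Biomonitoring Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Tradescantia clone 4430 stamen-hair mutation
    bioassay (Trad-SHM) read out by computer vision. Generates labeled
    synthetic single-cell images with the color structure of blue and pink
    stamen-hair cells, classifies cells with an RGB-interval baseline model
    and three convolutional network architectures (TinyVGG, VGG16 with batch
    normalization, ResNet34) trained by a compact built-in engine, and fits
    the biomonitoring statistics: a saturating dose-response curve for
    diesel-contaminated soil, backward-sliding-window particulate-matter
    averaging, and origin-constrained exposure regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
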