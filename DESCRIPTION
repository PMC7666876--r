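Package: melsci
Title: Multi-Exposure Laser Speckle Contrast Imaging Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for multi-exposure laser speckle
    contrast imaging (MELSCI) of microcirculatory perfusion. Synthesizes
    exposure times of 1 to 64 ms by recursive pairwise summation of 1-ms
    frames, computes squared speckle contrast in non-overlapping 4x4 pixel
    blocks, fits and applies a joint shot/dark/fixed-pattern camera noise
    model across all exposures, normalizes by the maximum contrast of a
    static target, and estimates perfusion per pixel with either of two
    single-exposure models or a small neural network operating on the full
    multi-exposure contrast curve. A dynamic-speckle simulator with known
    decorrelation time, dynamic fraction and camera noise provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
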