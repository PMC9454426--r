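Package: maldinet
Title: Deep-Learning Tumor Subtyping for MALDI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for multi-class tissue classification of
    MALDI mass spectrometry imaging (MSI) data from tissue microarrays:
    imzML input/output, spectrum re-binning onto an equidistant m/z axis,
    per-pixel min-max normalization, matrix-peak correlation filtering,
    a 1-D convolutional neural network trained under stratified k-fold
    cross-validation, DeepLift feature attribution for discriminative-mass
    discovery, duplicate-mass artifact filtering, density-preserving 2-D
    embedding of the selected masses, and spatial reporting (classification
    maps, core-level majority votes, ion images). Includes a synthetic
    tissue-microarray generator with planted class-marker masses,
    matrix-correlated peak families and off-tissue pixels, used as ground
    truth for feature-recovery and accuracy experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
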