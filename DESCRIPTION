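Package: cowseg
Title: Multitask Convolutional Segmentation of the Circle of Willis on
    Synthetic CTA Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to study automatic segmentation and anatomical-variant
    statistics of the Circle of Willis (CoW) on computed tomography
    angiography (CTA)-like data. Provides a synthetic head-neck CTA phantom
    generator with exact vessel ground truth and configurable per-segment
    absence, hypoplasia and focal stenosis; isotropic resampling, intensity
    windowing and axial patch extraction; a from-scratch multitask
    encoder-decoder network with atrous spatial pyramid pooling trained with
    a joint reconstruction-plus-Dice loss, and a single-task baseline; Dice
    and per-segment detection metrics; NASCET stenosis grading,
    variant/completeness classification, and chi-square / t-test group
    comparisons of prevalence summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
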