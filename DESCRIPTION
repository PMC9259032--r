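Package: craniomorph
Title: Euclidean Distance Matrix Analysis and Morphological Integration
    for 3D Landmark Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Superimposition-free landmark morphometrics for comparing
    craniofacial form between groups. Converts 3D landmark configurations
    into matrices of all unique inter-landmark distances, estimates
    form-difference matrices with nonparametric bootstrap confidence
    intervals, performs an overall bootstrap test of form difference,
    compares morphological integration between groups via bootstrap
    correlation-difference matrices, runs principal components analysis of
    ln-transformed inter-landmark distances, and provides Mann-Whitney U
    group comparisons plus suture-patency encoding. Ships built-in
    chondrocranial and dermatocranial landmark-set definitions for the
    embryonic mouse skull and a synthetic landmark-data generator for
    testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
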