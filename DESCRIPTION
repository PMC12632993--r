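Package: rdmem
Title: Lossy Compression Models of Mnemonic Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a rate-distortion account of mnemonic discrimination.
    Estimates the lossiness of compressing target images into similar lure
    images from embedding geometry by fitting a capacity-limited information
    channel (Blahut fixed point) to simulated confusion matrices; trains
    small autoencoders and beta-variational autoencoders to trace per-image
    rate-distortion curves and their normalized rate (slope); scores
    Mnemonic Similarity Task behavior (lure discrimination index,
    recognition, lure false alarms, quality control); computes neural
    signatures of compression (participation-ratio dimensionality,
    dimensionality differences between correct and incorrect lure trials,
    binned mutual information) under voxel subsampling; and relates the
    pieces statistically with mixed-effects models, penalized-spline
    generalized additive models, multiplicity correction and bootstrap
    contrasts. Ships synthetic-data generators with planted ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
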