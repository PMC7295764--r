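Package: spheroquant
Title: Quantification of Interstitial-Flow-Driven Tumor Spheroid Dissociation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify tumor spheroid dissociation and invasion from
    two-channel time-lapse fluorescence microscopy: azimuthally averaged radial
    cell-density profiles with Gaussian size fitting, single-cell tracking with
    speed, mean-squared-displacement and diffusion-coefficient estimation,
    flow-axis directional statistics, ellipse-based amoeboid/mesenchymal
    morphology classification, and marker-intensity quantification from
    confocal z-stacks. Includes a synthetic phantom generator producing every
    input the pipeline consumes together with ground-truth sidecars, so that
    each estimator can be validated against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
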