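Package: hsiStress
Title: Hyperspectral Image Analysis for Plant Heat-Stress Phenotyping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for classifying plant heat-stress status from
    visible/near-infrared and short-wave infrared hyperspectral
    reflectance images. Implements white/dark reflectance calibration and
    ENVI cube input/output, leaf segmentation and per-leaf mean-spectrum
    extraction, continuous class-code encodings for multi-group PLS
    discriminant analysis (linear-discriminant best projection values and
    sequential placement at regular intervals), NIPALS PLS1 modelling with
    variable-importance-in-projection scoring, ensemble waveband selection
    combining a VIP threshold filter with the successive projections
    algorithm, and pixel-wise chemical imaging of predicted stress codes.
    Includes a class-structured synthetic leaf-spectrum and cube generator
    with known ground truth for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
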