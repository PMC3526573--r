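Package: ColonyQuant
Title: Texture-Based Detection and Quantification of Stem-Cell Colonies
    in Phase-Contrast Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies colony-forming cells co-cultured on a
    feeder layer in phase-contrast microscopy images. Each pixel is
    characterised by multiscale Basic Image Features (a seven-way local
    symmetry classification derived from scale-normalised
    derivative-of-Gaussian responses) summarised into local-histogram
    feature vectors, and labelled colony or background by a random-forest
    classifier. Binary morphology removes detection noise and fills small
    holes before colony counts, areas and confluency are reported. A
    procedural generator produces two-texture synthetic images with ground
    truth masks for training and validation, and a companion module
    implements the analytical perfusion-physics calculations (parallel-plate
    wall shear stress, residence time, media-exchange rate) for the
    perfused culture chamber the imaging supports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    randomForest,
    png,
    tiff,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Classification, Segmentation, Visualization
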