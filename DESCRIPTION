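Package: tumortex
Title: Grey-Level Co-Occurrence Texture Features and Neuro-Fuzzy
    Classification of Brain MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for texture-based detection and grading of brain tumours
    in grey-scale magnetic resonance images. Implements Gaussian smoothing
    and unsharp-mask enhancement, grey-level co-occurrence matrices (GLCM)
    in four orientations plus their average with the classical set of 14
    Haralick-style texture statistics, concentration-threshold segmentation
    with morphological clean-up and hole filling, and an adaptive
    neuro-fuzzy inference system (ANFIS) classifier trained by gradient
    descent with momentum that labels an image as normal, benign or
    malignant. Includes a seeded synthetic-texture generator emulating the
    three image classes so the full pipeline can be exercised and evaluated
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
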