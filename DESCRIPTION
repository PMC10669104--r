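Package: spermtrack
Title: Sperm Detection, Tracking and Motility Analysis from Microscopy Video
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale computer-assisted sperm analysis (CASA) toolkit for
    brightfield microscopy video of boar sperm. Counts total sperm in single
    frames (Otsu segmentation, morphological cleaning, connected components),
    detects moving sperm with an adaptive per-pixel Gaussian-mixture
    background model, tracks identities with a constant-velocity Kalman
    filter and Hungarian assignment, computes per-track kinematic parameters
    (VCL, VSL, VAP, LIN, STR, WOB) with WHO-style A-D motility grading, and
    scores frame sharpness with SMD- and Tenengrad-based focus measures.
    A seeded synthetic-video generator with exact ground truth makes every
    pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
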