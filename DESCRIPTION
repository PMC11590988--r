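Package: caprimon
Title: Lightweight Behavior Detection and Monitoring for Housed Cashmere Goats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for camera-based behavior monitoring of housed cashmere
    goats. Implements a lightweight one-stage anchor-free detector family
    (a compact baseline plus Ghost-convolution, slim-neck, and hybrid
    variants with pluggable feature-pyramid attention), the bounding-box
    regression losses used to train it (IoU, CIoU, EIoU, SIoU, Alpha-CIoU,
    distribution focal loss), CLAHE night-image enhancement with edge-based
    contrast and discrete-entropy metrics, label-preserving augmentation
    operators (vertical stitching, mosaic, mixup), Pascal VOC and YOLO
    annotation I/O, a seeded synthetic pen-scene generator for fully
    reproducible testing, and an online per-second behavior-record pipeline
    with ethogram time budgets and a VOC-style mAP evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    png
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
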