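Package: ovometry
Title: Single-View Metrology for Egg Size Measurement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures an egg's major and minor axes from a single perspective
    image using cross-ratio length transfer along the vanishing line of a
    reference plane. Provides homogeneous 2-D projective geometry primitives,
    a MLESAC-style vanishing-point estimator driven by cross-parallel
    reference cards, interplanar distance recovery, label-mask ingestion with
    a classical colour-threshold segmentation fallback, a pinhole-camera
    scene simulator (prolate-spheroid egg resting in a V-groove carrier) that
    emits exact ground truth for every image-side quantity, and evaluation
    utilities (IoU, pixel accuracy, measurement-error summaries, ordinary
    least squares agreement reports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
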