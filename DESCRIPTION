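Package: SEIgait
Title: Skeleton Energy Images for Video-Based Gait Severity Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pipeline for classifying Parkinson's disease gait severity
    (normal, mild, moderate, severe; UPDRS gait scores 0-3) from human-pose
    key points extracted from walking videos. Implements confidence-based
    key-point filtering, height-normalized headless skeleton rasterization,
    skeleton energy image (SEI) synthesis with a 17-frame rolling kernel, a
    key-frame variant driven by inter-frame differencing, imbalanced and
    oversample-balanced dataset construction with deterministic 8:1:1 splits,
    and shallow image classifiers (CNN, ResNet, Vision Transformer families)
    trained with AdamW, cross-entropy and patience-based early stopping. A
    parametric sagittal-plane gait simulator generates labeled 12-joint pose
    sequences with severity-dependent kinematics so the full pipeline is
    exercisable without clinical video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
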