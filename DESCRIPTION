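Package: neuromorph
Title: Machine-Learning Morphometry of Peripheral Nerve Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-forest pixel segmentation of Elastica-van-Gieson-like nerve
    cross-section images into six tissue classes, roundness-based
    reclassification of nervous-tissue components into organized fascicles
    versus unorganized (neuroma) tissue, per-sample tissue-composition
    quantification including a normalized deviation index, and
    normality-gated group-comparison and pain-correlation statistics.
    Includes a synthetic cohort generator that renders nerve cross-sections
    with exact ground-truth masks and clinical metadata, so the whole
    pipeline is testable end-to-end without any slide data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    ranger,
    rlang,
    png,
    tiff,
    jsonlite,
    nortest,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
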