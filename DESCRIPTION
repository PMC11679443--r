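Package: welfaremetrics
Title: Camera-Based Welfare Analytics for Dairy Cattle and Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytic core of a video-based livestock welfare monitoring
    pipeline. Consumes per-frame pose keypoints, detector/tracker outputs
    and pen configuration (not raw video) and computes cattle locomotion
    features with rolling-window lameness scoring, open-set markerless
    identification via centroid anchor dictionaries, pig activity budgets
    and travel distance through pixel-to-world homography, rule-based
    social and enrichment interaction detection with SSIM confirmation,
    and CIEDE2000 colour-template identification. Includes seeded
    synthetic-fixture generators for every input so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    nnet,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
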