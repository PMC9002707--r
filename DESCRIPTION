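Package: pigcount
Title: Tracking-Based Pig Counting for Hallway Surveillance Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for counting pigs that walk through a farm hallway under a
    wall-mounted grayscale camera, built on a tracking-by-detection pipeline.
    Provides a lightweight multi-object tracker (constant-velocity Kalman
    filtering, Mahalanobis-gated appearance matching with a flattened 10x10
    grayscale crop descriptor, Hungarian assignment with an age-cascaded
    matching scheme), a line-crossing counting state machine that tallies
    signed entrance-to-exit crossings over all tracks, a filter-clustering
    pruning algorithm for 3x3 convolution layers with shape propagation over a
    darknet-style layer graph, CLEAR-MOT tracking metrics and a counting
    accuracy score, and a deterministic synthetic hallway scene generator so
    the whole pipeline is testable without video data or a trained detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
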