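Package: brushtrack
Title: Hierarchical Toothbrushing-Region Recognition from Dual IMU Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for fine-grained recognition of toothbrushing regions from
    inertial measurement unit (IMU) recordings taken by a toothbrush-mounted
    sensor and a wrist-worn sensor. Provides sliding-window time-domain feature
    extraction over derived signal channels (vector norms, anatomical-plane
    projections, quaternion-derived Euler angles), a two-stage hierarchical
    classifier that first separates brushing from transition windows and then
    assigns one of 18 dental regions, temporal post-processing (contextual
    smoothing and per-segment majority voting), leave-one-session-out
    cross-validation with confusion-matrix metrics, and a synthetic
    brushing-session simulator that generates labelled dual-stream sessions for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
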