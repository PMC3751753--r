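Package: imucap
Title: Motor-Capacity Assessment from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates motor capacity of rehabilitation patients from
    wrist-, hip- and foot-worn inertial measurement units (IMUs). Provides
    orientation-robust signal preprocessing (magnitude series, zero-phase
    low-pass filtering, automatic task-boundary detection from a labeling
    sensor), a per-task feature set (task completion time, movement
    intensity and its variation, dominant frequency, spectral movement
    smoothness, rotation energy, angular-velocity range, wheelchair
    push-cycle arm synchrony via sliding-window-and-bottom-up segmentation,
    and heel-strike-based gait step and stance parameters), and a
    significance-gated linear capacity model evaluated by
    leave-one-session-out cross-validation. A synthetic-session generator
    with full ground truth makes every stage testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
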