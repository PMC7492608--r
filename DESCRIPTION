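Package: pmbr
Title: Post-Movement Beta Rebound Dynamics in Real-World Motor Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-by-trial post-movement beta rebound
    (PMBR) dynamics during real-world motor-skill learning in a billiards-style
    task. Provides a synthetic-cohort generator (signed directional errors with
    decaying bias/variability and AR(1) structure, single-channel EEG with
    programmed beta bursts, joint-velocity kinematics with controllable
    effective dimensionality, ball-tracking coordinates), ball-tracking onset
    detection and directional-error geometry, Morlet time-frequency analysis
    with block-relative log-power normalization and per-trial PMBR extraction,
    behavioral skill-learning metrics (learning rate, intertrial variability,
    lag-1 autocorrelation over session halves, manipulative complexity), and
    data-driven bimodal grouping of learners via Gaussian-mixture model
    selection (AIC/AICc) and fuzzy c-means clustering with a within/between
    cluster validity index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
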