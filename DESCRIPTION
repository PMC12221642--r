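Package: gazeflock
Title: Gaze-Following Analysis for Motion-Captured Bird Flocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying gaze following in flocks of
    birds tracked with marker-based motion capture. Reconstructs a per-frame
    head-local coordinate system from four rigid head markers and an
    eye/beak calibration, reprojects foveal and binocular visual-field cones
    into the world frame, intersects them with spherical regions of interest
    to segment filtered looking bouts, assembles per-observer
    per-presentation response tables with demonstrator counts and exclusion
    rules, and fits binomial and Poisson generalized linear mixed models of
    the condition and demonstrator-count effects (including linear versus
    quadratic model comparison and simulation-based confidence intervals).
    A synthetic-data module generates marker trajectories and response
    tables with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
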