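Package: quieteye
Title: Automated Quiet-Eye Measurement from Gaze and Club Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automated measurement of the quiet-eye period (the final
    pre-movement fixation on the action target) from head-mounted
    eye-tracking and club kinematics in virtual-reality golf putting.
    Provides zero-phase filtering primitives, world-frame gaze geometry,
    dispersion-threshold (I-DT) fixation detection, kinematic event
    detection (backswing onset, ball contact), quiet-eye scoring with
    early/online/dwell phase decomposition, putting performance measures
    (radial error, 95 percent confidence ellipse), outlier Winsorization,
    linear mixed-effects condition contrasts with standardized effect
    sizes and marginal/conditional R-squared, and Monte-Carlo power
    simulation. A synthetic trial generator plants ground-truth
    fixations, swings, and outcome effects so every pipeline stage is
    verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
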