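Package: balancegait
Title: Visually Induced Balance Responses During Treadmill Walking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for visually induced balance responses during
    treadmill walking: rotation stimulus waveform and heelstrike-triggered
    randomized scheduling, gait event detection from marker kinematics
    (prominence-based heelstrike and pushoff rules), Butterworth filtering and
    spline gap filling, center-of-mass and center-of-pressure computation, EMG
    conditioning, step segmentation with 100-point time normalization,
    control-step baselines with toward/away mirroring, a CoM-state linear
    foot-placement model with stimulus-induced foot-placement estimates,
    response-onset estimation by tangent extrapolation, linear mixed-effects
    inference with least-squares means, and simulation-based power analysis.
    Includes a kinematic synthetic walker with known ground truth so the whole
    chain is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    emmeans,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    yaml
Suggests:
    pbkrtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
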