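Package: dvjmech
Title: Drop Vertical Jump Landing Biomechanics and Muscle-Damage Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for sagittal-plane drop vertical jump (DVJ)
    landing biomechanics: ground-reaction-force event detection, zero-lag
    Butterworth filtering, marker-based joint kinematics, planar bottom-up
    Newton-Euler inverse dynamics, phase segmentation, knee joint stiffness
    and jump height, together with the statistics used to study
    exercise-induced muscle damage (test-retest reliability via CV, SEm and
    ICC, repeated-measures ANOVA, paired t-tests, percent change and paired
    power analysis). A dynamically self-consistent synthetic motion-capture
    generator produces marker and force-plate recordings under configurable
    baseline and muscle-damaged condition presets, so the full pipeline can
    be exercised and validated without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
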