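Package: saltijump
Title: Jump Kinematics and Leg Choreography of Jumping Spiders from Tracked Video Points
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for take-off kinematics of jumping spiders
    (Salticidae) filmed in profile at high frame rates. Reads digitized
    tracked-point tables (centre of mass and per-leg joints), detects jump
    events (movement onset, per-leg lift-off, all-legs-off, peak
    acceleration), computes the standard kinematic panel (take-off duration,
    velocity, acceleration, kinetic energy, force, power, g-force, take-off
    angle, trajectory heights), quantifies leg-extension choreography via
    effective leg length and joint angles, classifies the propulsive leg,
    and runs the accompanying statistics (circular summaries and the
    Watson-Williams test for take-off angles; mass-by-sex linear mixed
    models with AIC selection; Mann-Whitney comparisons). A ground-truthed
    synthetic jump simulator with articulated three-segment legs supports
    validation, and body-only centre-of-mass geometry is computed from
    labelled voxel volumes or watertight triangle meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
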