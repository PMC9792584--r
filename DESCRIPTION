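Package: sescom
Title: Subject-Specific Whole-Body Center-of-Mass Estimation with
    Statically Equivalent Serial Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the whole-body center of mass (CoM) of a
    branched rigid-body model of the human body. Implements the statically
    equivalent serial chain (SESC) reparameterization, in which the CoM of a
    branched kinematic chain is expressed as the end-effector of a virtual
    serial chain whose constant link vectors are identified from static
    postures and center-of-pressure (CoP) readings by linear least squares.
    Includes forward kinematics for branched trees of spherical and hinge
    joints, static-posture detection from joint-angle and CoP streams, a
    table-driven segmental-analysis comparator, method-agreement statistics
    (per-axis RMSE, Bland-Altman fixed and proportional bias, group
    comparisons), and a synthetic humanoid data generator with fit and obese
    mass-distribution presets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lmtest,
    sandwich,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
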