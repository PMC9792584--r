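---
title: "Whole-body CoM estimation with statically equivalent serial chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body CoM estimation with statically equivalent serial chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sescom)
```

## The model

The whole-body center of mass (CoM) of a rigid-body model with `n`
segments is the mass-weighted sum of segment CoMs,

$$\overrightarrow{CoM} = \frac{1}{M}\sum_{i=1}^{n} m_i\,\vec p_i,
\qquad M = \sum_i m_i,$$

where each segment's global CoM position $\vec p_i$ is obtained by
carrying its constant local offset $\vec C_i$ through the chain of
homogeneous transforms $(R_i, \vec d_i)$ from the root to the segment.
`brute_force_com()` evaluates this directly and is the package's
ground-truth forward model.

Expanding the products and collecting the constant coefficients turns
the same quantity into the end-effector of a virtual *serial* chain:

$$\overrightarrow{CoM} = \vec d_1 + R_1\vec v_1 + R_1 R_2\vec v_2 +
\dots = [\,I \;\; \hat R\,]\begin{bmatrix}\vec d_1\\ \vec V\end{bmatrix},$$

with $\hat R$ the $3\times 3n$ matrix of cumulative root-to-body
rotations and $\vec V$ a constant $3n$-vector. Collecting coefficients
gives the closed form implemented in `sesc_vector_from_parameters()`:

$$\vec v_j = \frac{1}{M}\Big(m_j \vec C_j +
\sum_{c\,\in\,\mathrm{children}(j)} M_{\mathrm{subtree}(c)}\,\vec d_c\Big).$$

This identity is not taken on faith: the test suite verifies, on random
branched instances, that the serial-chain form reproduces the weighted
sum to $10^{-12}$ m, against two independent 4×4 homogeneous-matrix
oracles.

Because $\vec V$ is constant per subject and the model is linear in
$(\vec d_1, \vec V)$, a force platform provides the calibration signal:
in static equilibrium the center of pressure (CoP) is the horizontal
projection of the CoM. Each held posture therefore contributes the AP
and ML rows of $\hat R$ and the right-hand side
$\mathrm{CoP}-\vec d_{1,xy}$ to a stacked least-squares system
(`stack_system()`), solved in `identify_sesc()` by the Moore–Penrose
pseudoinverse (SVD with a relative singular-value cutoff of
$10^{-10}$). With two equations per posture and $3n$ unknowns, at least
$\lceil 3n/2\rceil$ postures are required — 14 for the default
nine-body model (`minimum_postures(9)`).

## Coordinate and sign conventions

- Global axes: `x` = anteroposterior (AP, anterior positive), `y` =
  mediolateral (ML), `z` = vertical up. "Horizontal" always means the
  (x, y) rows.
- Internal units are meters; evaluation statistics are reported in
  millimeters.
- Joint rotations are stored as full rotation matrices; intrinsic
  Z-X-Y Euler and quaternion constructors are provided at the I/O
  boundary, since IMU systems differ in parameterization.
- Bland–Altman differences are estimate − reference, sample (n−1)
  standard deviations are used everywhere, limits of agreement are
  bias ± 1.96·SD, and the bias CI defaults to the normal approximation
  bias ± 1.96·SD/√n (a t-based CI is available by flag).

The n−1 convention is not arbitrary: applied to the bundled
per-subject RMSE transcription (`load_rmse_table()`), it reproduces the
printed group SDs (e.g. ±6.64 mm for the fit-group AP column), whereas
the population formula does not.

## The default tree and its identifiability

`default_tree()` has a pelvis root with a free 6-DoF pose, two
three-link legs (spherical hip, hinge knee and ankle about the parent
ML axis), and two spherical single-link branches for the trunk/head and
the lumped upper limbs — 19 joint DoF. The tree is fully configurable
(`kinematic_tree()`, JSON I/O), so alternative segmentations can be
instantiated without code change.

One structural fact matters for interpretation: a hinge rotation fixes
its own axis, so for a chain of hinges sharing an axis the link
components along that axis enter the regressor through identical
columns, and only their *sum* is observable. Likewise the component of
$\vec v_1$ along any direction in which the root never rotates is
confounded with $\vec d_1$. The stacked design for the default tree
therefore has rank 23 of 27 even with perfectly diverse postures.
`identify_sesc()` reports the rank and warns; the minimum-norm solution
it returns predicts the CoM exactly for any reachable posture — the
noiseless held-out error in the tests is at numerical precision — so
the deficiency affects parameter attribution, not estimation. The
pipeline helpers (`run_subject_pipeline()`, `run_stream_pipeline()`)
suppress the warning and surface the rank in their results.

## Static-posture detection

`detect_static_postures()` scans synchronized angle (degrees) and CoP
(mm) streams in non-overlapping windows — defaults 1 s at 60 Hz — and
marks a window static when every angle channel's SD is below 1.5° and
the CoP SD below 6 mm. Decisions taken where the protocol leaves room:

- The angle criterion is enforced per channel (a moving limb cannot
  hide in an aggregate), with SDs computed on wrapped differences so
  ±180° crossings are not flagged as motion.
- The CoP criterion is enforced per axis by default; a resultant-
  displacement mode is available (`cop_mode = "resultant"`).
- Window stride is one full window; a sliding mode with greedy
  non-overlap resolution exists behind a flag.
- Runs of adjacent static windows are merged into maximal static
  regions; one representative observation (per-channel mean) is
  reported per region, so a posture held for several seconds counts
  once.

## The synthetic generator

No recorded trials ship with the package, so `make_subject()`,
`sample_static_postures()`, `simulate_trial()` and
`expand_to_time_series()` generate everything the pipeline consumes,
with the ground truth retained for recovery tests.

What it emulates, and the defaults chosen where the protocol gives
none (all are arguments, chosen once and not tuned per test):

- Cohorts: `fit` subjects jitter baseline mass fractions by ±5%
  (renormalized), statures 1.60–1.90 m, masses 55–85 kg; `obese`
  subjects multiply the trunk-branch fractions (pelvis, trunk/head,
  upper limbs) by 1.4 before renormalizing, masses 90–130 kg — mass
  redistribution at unchanged geometry.
- Postures: spherical joints uniform ±30° per Euler axis, knees 0–60°
  flexion, ankles ±20°, and a ±15° root (pelvis) orientation range —
  subjects lean while posing, which is also what makes the root link
  observable from horizontal CoP.
- Sensors: CoP noise 2 mm SD, joint-orientation noise 0.5° SD applied
  as a small random rotation composed with the true rotation (hinge
  joints are perturbed within their axis, keeping postures valid).
  These are instrument-grade artifact choices; no noise magnitudes are
  part of the protocol itself.
- Streams: each observation becomes a 2 s plateau with sub-threshold
  jitter joined by 1 s transitions carrying a 25°/50 mm half-sine
  excursion, at 60 Hz. With these durations the plateau boundaries
  align with the 1 s window grid and the detector recovers exactly one
  region per input posture; the jitter can be set to zero for
  numerically exact round trips.

What it does *not* model: physiologically validated obesity geometry,
support-polygon constraints on the CoP, soft-tissue artifact,
sensor-to-segment misalignment, and any dynamic (accelerated) motion.
Passing tests therefore demonstrate the estimator's statistical
machinery under the stated assumptions, not field accuracy on human
recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run the identification at
m = 40 (noiseless), m = 80–100 (noisy) postures per subject, 50 seeded
replicates for stochastic claims, and 10⁴ postures for the
law-of-large-numbers check of the noise calibration — sizes chosen so
the full suite completes in about two minutes on one CPU while leaving
the stochastic bounds comfortably away from their thresholds.

Other numerical decisions: the pseudoinverse cutoff is relative
($10^{-10}\cdot\sigma_{\max}$); the 75/25 split size is rounded half
away from zero and the split is random under a recorded seed (a
sequential mode exists); posture distinctness is diagnosed via rank and
condition number rather than filtered; degenerate inputs (identical
postures, zero-variance comparisons) produce warnings or explicit
degenerate reports, never silent failures.

## The comparator and the headline contrast

The segmental comparator (`segmental_com()`) is a generic table-driven
estimator over the same tree: masses from table fractions, CoMs at a
ratio of segment length along a declared axis, joints placed by
direction-and-scale entries — an `anthropometric_table()` can encode a
subject exactly (`table_from_parameters()`), which is how calibrated
and mis-calibrated tables are constructed in simulations. A
proprietary multi-segment commercial implementation is deliberately
out of scope; the comparator isolates the one property under study,
dependence on assumed mass distribution.

The package's central reproducible contrast, computed by
`scripts/acceptance.R` and asserted property-style in the tests: on
obese-preset subjects with a fit-calibrated table, the segmental
estimator's anteroposterior |fixed bias| exceeds the identified
estimator's in at least 90% of seeded runs (agreement is assessed per
axis; the trunk-dominant redistribution acts along AP, while the
generator's ML plane is symmetric so both methods are near-unbiased
there), while the identified estimator's RMSE
distributions for fit and obese subjects are statistically
indistinguishable at α = 0.05 — subject-specific identification
absorbs the mass redistribution that defeats table-based estimation.

## Known limitations

- Static conditions only; no velocity/acceleration kinematics, ZMP or
  extrapolated-CoM quantities.
- Vertical CoM accuracy is never validated against an external
  reference (the CoP carries no vertical information); the vertical
  component of the prediction inherits whatever the minimum-norm
  solution assigns to the unobservable directions.
- The rank deficiency discussed above means identified link vectors
  are not individually interpretable for hinge chains; compare
  predictions, not parameters.
- The obese preset is a caricature (one multiplicative factor on the
  trunk branch); it is designed to make the comparator's failure mode
  visible, not to model obesity.
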