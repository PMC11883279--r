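---
title: "Jump kinematics and leg choreography from tracked points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jump kinematics and leg choreography from tracked points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltijump)
```

## The analysis

Jumping spiders (Salticidae) power their jumps with a semi-hydraulic
mechanism: haemolymph pressure generated by cephalothorax muscles extends
legs that have no extensor muscles of their own. The observable signature
of a jump, filmed in profile at 5000 frames s^-1^, is a set of digitized
point tracks: the centre of mass (CoM, located beforehand on a segmented
micro-CT volume with the legs excluded) and four joints per leg
(trochanto-femoral, femoro-patellar, tibio-metatarsal, tarsal claw).

From the CoM track this package computes, per jump:

* **take-off duration** — from the first frame with CoM movement to the
  first frame with all legs off the substrate;
* **take-off velocity** `v = d/t` per frame (path speed, the norm of the
  planar displacement over the frame interval) and its maximum;
* **acceleration** `a = dv/dt` per frame and its peak;
* the derived identities **ke = 1/2 m v²** (µJ), **F = m a** (mN),
  **P = ke/duration** (mW) and **g-force = a/9.81**, with mass in mg
  converted to SI internally;
* **take-off angle** — the elevation of the CoM displacement between the
  last frame before the abdomen moves and the all-legs-off frame,
  measured against the substrate plane;
* **trajectory peak and end heights** for clips spanning the full gap.

From the leg tracks it computes the **effective leg length**
(ELL = trochanter-to-claw chord over the summed segment lengths; 1 means
fully extended), the **joint angle** at the femoro-patellar joint, per-leg
lift-off, and offsets of lift-off and maximum extension from the
peak-acceleration instant. The **propulsive leg** is the leg that is last
to leave the substrate *and* reaches maximum extension after peak
acceleration — the leg still driving the body when the others are
airborne (leg III in *Maratus*; leg IV in *Attulus*-like choreographies,
which the classifier reports equally well).

## Event detection and its parameters

Published analyses identify events visually; on digitized tracks they
must be operationalized. Defaults (all exposed in `run_config()`):

| parameter | default | meaning |
|---|---|---|
| `onset_baseline` | 50 frames | stationary window defining the noise floor |
| `onset_k` | 3 | onset threshold = baseline mean + k × s.d. of frame-to-frame displacement |
| `onset_persist` | 5 frames | frames the threshold must hold |
| `liftoff_height` | 0.05 mm | claw height above the platform that counts as airborne |
| `liftoff_persist` | 3 frames | frames the height must hold |
| `smooth_window` | 1 (off) | centered moving average on positions before differencing |

The onset threshold includes the baseline *mean* displacement, not only
k standard deviations: displacement magnitudes are positive-valued under
noise, and a bare k·σ rule fires constantly inside the baseline. On
noise-free tracks the rule degenerates to "any movement", which is exact.

Two practical consequences are documented rather than hidden. First, at
0.2 ms intervals raw double-differencing amplifies tracking jitter by
roughly √2/Δt²: 2 µm of jitter produces spurious accelerations of
hundreds of m s^-2^. A smoothing window of 5–9 frames keeps the
peak-acceleration bias at a few percent on synthetic data; the default is
*off* so that clean tracks are differentiated exactly as defined. Second,
for stance profiles that rise gently from zero, a threshold detector
necessarily fires only once the motion clears the noise floor, so noisy
take-off durations are biased short. Noise-free event recovery is exact
to within one frame.

## The synthetic jump generator

No raw tracking data are deposited for any published salticid jump study,
so validation rests on a ground-truthed simulator whose defaults *are*
the published sex-mean study conditions for *M. splendens*
(`default_sim_params()`): male 4.9 mg, 127.8 m s^-2^, 0.84 m s^-1^,
20.8 ms, 25.08°, III–IV lift-off lag 3.8 ms; female 10.4 mg,
122.7 m s^-2^, 0.81 m s^-1^, 24.6 ms, 20.89°, lag 3.5 ms; 5000 frames
s^-1^; 40 mm gap.

The simulation is *prescribed-kinematics*, not force-based: the
semi-hydraulic mechanism is not modelled, only the observable tracks the
analysis consumes. Choices worth knowing:

* **Stance acceleration profile.** The three stance statistics reported
  together (peak acceleration A, take-off velocity v, duration T) do not
  determine a waveform. We use a power ramp `A (t/t_p)^p` to the peak at
  `t_p = 0.85 T`, then a linear descent to zero at T, with p solved so
  the profile integrates to v. The 0.85 peak fraction places peak
  acceleration ~3 ms before all-legs-off, the timing reported for leg
  III. Both the family and the fraction are exposed parameters; the
  feasible velocity interval for given (A, T, fraction) is checked and
  reported.
* **Discrete integration on the frame grid.** Acceleration is sampled at
  frame times (peak snapped to the grid) and accumulated per frame, so
  the first-difference estimators recover the prescribed peak exactly at
  the native frame rate; the velocity integral then matches the target
  to O(Δt²). Flight is exact closed-form ballistics at 9.81 m s^-2^,
  sampled until the horizontal displacement spans the gap.
* **Legs.** Each leg is a planar three-segment chain: the femur and the
  combined lower leg form a knee-up triangle whose chord is driven by a
  monotone ELL schedule (initial ELL 0.55 rising to exactly 1.0 at the
  scheduled full-extension time). The claw stays pinned on the platform
  until the scheduled lift-off, after which the chain translates with the
  body. Legs I/II are generated raised-and-extended from frame 0 — the
  posture held before take-off — and have no free schedule. Leg IV fully
  extends ~1 ms before peak acceleration and lifts off `leg_lag_ms`
  before leg III; leg III extends through to its lift-off at stance end,
  so its maximum ELL falls after the peak. Schedule times are snapped to
  the frame grid, so a 3.5 ms lag (17.5 frames) is realised as 18 frames.
* **Tracking noise** is i.i.d. Gaussian per coordinate (the
  manual-digitization error model), seeded and reproducible. The cohort
  default of 2 µm reflects careful sub-pixel digitization at the study's
  optical scale.

What the generator does **not** emulate: lens distortion and perspective,
autocorrelated digitization error, out-of-plane (3D) leg motion, body
pitch, drag, silk drag-line forces, or landing. Passing recovery tests
therefore demonstrates that the estimators are correct for planar,
frame-sampled kinematics with independent jitter — not that every
real-world artefact is handled.

## Statistics

* **Circular statistics.** Take-off angles are summarised by the circular
  mean and mean resultant length r, and compared between sexes with the
  Watson–Williams F test, `F = K (N−2)(R₁+R₂−R)/(N−R₁−R₂)` on (1, N−2)
  d.f., with `K = 1 + 3/(8κ̂)` and κ̂ from the standard piecewise ML
  approximation of the von Mises concentration (the three-regime formula
  in `kappa_ml`); a flag warns when the pooled mean resultant length
  drops below 0.75, where the test's concentrated-data assumption is
  doubtful. A seeded Best–Fisher von Mises sampler supports calibration
  tests (type-I error within [0.035, 0.065] at κ = 20, n = 30/30 over
  2000 replicates).
* **Mixed models.** Each kinematic response is modelled as
  `response ~ mass + sex (+ mass:sex)` with a subject random intercept,
  fitted by maximum likelihood through lme4/lmerTest — ML, not REML,
  because the AIC comparison is between models differing in fixed
  effects. Ties in AIC go to the additive model. Fixed-effect tests use
  Satterthwaite denominator d.f.; the method is recorded in the fit.
  Responses are natural-log transformed by default (the natural scale
  for positive kinematic magnitudes); the flag is recorded in output
  because published reports are often silent about it.
* **Mann–Whitney.** U is the smaller group statistic under midranks;
  p is exact by permutation enumeration for combined n ≤ 20 and a
  tie-corrected normal approximation beyond.

## Centre-of-mass geometry

The body-only CoM comes from a labelled voxel grid (legs in a separate
label, excluded; uniform density inside included labels — the
homogeneous-and-solid assumption) or from a watertight triangle mesh via
signed-tetrahedron decomposition, which is independent of the reference
point for a closed, consistently oriented mesh; watertightness is checked
fail-closed (every undirected edge shared by exactly two opposed
triangles). Block-majority binning (ties to the lowest label) mirrors the
resolution-halving step of the scan-processing workflow. The two CoM
routes agree within half a voxel on voxelized solids, which is the
cross-method acceptance check.

## Numerical choices and degenerate inputs

* Ties in argmax (peak acceleration, maximum ELL) resolve to the earliest
  frame.
* Interior CoM tracking gaps of ≤ 3 frames are linearly interpolated with
  a warning; longer gaps leave the trial analyzable only up to the gap.
* ELL slightly above 1 under noise is retained and flagged (capped only
  for display).
* The take-off angle uses the horizontal displacement magnitude, so it is
  the elevation above the substrate regardless of jump direction, always
  in (−90°, 90°).
* Degenerate inputs error loudly: coincident calibration points,
  all-missing tracks, zero CoM displacement, open or inconsistently
  oriented meshes, empty label selections, infeasible stance statistics
  (with the achievable velocity interval in the message).

## Problem sizes

The bundled analysis and test runs use the study-shaped cohort — 10 male
subjects (30 jumps) and 12 female subjects (35 jumps) at 5000 frames
s^-1^, ~450 frames per trial — and keep the Monte-Carlo work at 2000
replicates for the circular-test calibration, 200 for mixed-model
recovery, and a few hundred for detector and selection checks. These
sizes give comfortable statistical resolution for the asserted bounds
while keeping a full run in the order of a minute.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_jump(default_sim_params("male"))
an <- analyze_trial(sim$trial)
an$metrics$takeoff_angle     # 25.078 deg, generator set 25.08
an$classification$propulsive_leg  # "L3"

cohort <- simulate_cohort(seed = 20)
out <- run_analyze(lapply(cohort, `[[`, "trial"),
                   config = run_config(smooth_window = 9L))
run_report(out$results)
```

## Known limitations

Single-camera profile-view geometry only (no 3D reconstruction); one
tracked leg per pair; threshold-based onset detection is biased late on
gently starting profiles under noise; peak acceleration from raw
differencing is noise-amplifying and from smoothed positions is biased
low — both trade-offs are parameterized, logged, and quantified on
synthetic data rather than silently chosen.
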