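---
title: "Methods: synthetic DVJ landings, planar inverse dynamics and the muscle-damage statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic DVJ landings, planar inverse dynamics and the muscle-damage statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvjmech)
```

# The analysis model

`dvjmech` analyzes bilateral drop-vertical-jump (DVJ) landings in the
sagittal plane. The processing chain and its conventions:

**Events on raw force.** Initial contact (IC) and take-off (TO) are the
first raw total vertical GRF samples strictly above, and back at or below,
a 10 N threshold, at the force rate (1000 Hz by default, 1 ms resolution).
A 20 ms debounce merges sub-debounce gaps and discards sub-debounce
blips — short enough to suppress threshold chatter from plate noise
(2 N RMS noise exceeds 10 N with probability ~3e-7 per sample), long
enough never to bridge a real flight phase (~200 ms or more). The first
above-threshold interval lasting at least 100 ms is the analyzed landing
contact; this excludes pre-contact spikes and the second landing after the
jump. Events are detected **before** filtering.

**Zero-lag filtering.** Markers and forces pass a Butterworth low-pass at
15 Hz applied forward and backward (zero phase) with odd-reflection edge
padding. "Fourth order" is interpreted as the net order after the dual
pass, i.e. a 2nd-order filter per pass — the dominant biomechanics
convention; `order_interpretation = "per_pass"` selects the alternative.
The dual-pass magnitude response is $|H(f)|^2 = 1/(1 + (f/f_c)^4)$, hence
gain 0.5 exactly at the cutoff. No cutoff-correction factor is applied.

**Kinematic conventions.** x is anterior, y vertical up, z mediolateral.
Knee flexion is the angle between the thigh line (hip–knee markers) and
the shank line (knee–ankle), zero at full extension, flexion positive.
Hip flexion is measured relative to the pelvis line; anterior pelvic tilt
is positive when the anterior pelvis markers sit below the posterior ones,
referenced to the lab horizontal (a static-calibrated pelvic reference is
a defensible alternative; the lab-horizontal convention was chosen because
the generator and the analyzer then share one definition with no extra
calibration input). The ankle angle is the shank–foot angle minus its
value in the subject's static standing trial, so neutral standing reads
0° and dorsiflexion is positive — consistent with a negative
(plantarflexed) ankle at initial contact. Angles come from marker-defined
segment lines rather than functional joint centres: functional calibration
needs 3D star-arc motions that a planar synthetic world cannot provide,
and the planar substitution keeps generation and analysis closed.

**Phases and metrics.** The landing phase runs from IC to the instant of
peak knee flexion (global maximum in the contact, earliest frame on ties,
found at the kinematic rate); propulsion from that instant to TO. Total
contact duration is measured at force-rate resolution; landing and
propulsion use the kinematic-rate peak instant, so the three durations are
additive by construction. Knee joint stiffness is
$K = (M_{pk} - M_{ic}) / (\theta_{pk} - \theta_{ic})$ in Nm/kg/deg with
moment and angle sampled **at** the two phase-boundary instants (a literal
reading of "moment change over the range of motion between the two
instants"); `stiffness_mode = "peak_ratio"` exposes the phase-extrema
alternative. Jump height is the rise of the mean of the four pelvis
markers above its static-standing value at the post-take-off apex, in cm.
Vertical GRF is reported per plate in multiples of body weight: the task
is bilateral, the load is shared, and a "2 BW" per-leg landing peak
corresponds to a ~4 BW whole-body peak.

**Inverse dynamics.** Bottom-up planar Newton–Euler recursion over foot,
shank and thigh of the dominant leg, with the plate under that leg
carrying half the total GRF (bilateral symmetric task). Segment masses,
CoM locations and radii of gyration come from published anthropometric
fraction tables shipped as plain text (`deleva1996` default, `dempster1955`
alternative); segment lengths are fixed stature fractions. Accelerations
are double-differentiated filtered marker positions (central differences),
matching the conventional processing order; the free moment is zero in a
planar model. Internal moments are reported extension-positive (hip,
knee) and plantarflexion-positive (ankle), and joint power
$P = M\,\omega$ uses matching angular-velocity conventions, so eccentric
absorption is negative. Moments and powers are normalized to whole-body
mass.

**Statistics.** Test–retest reliability: CV% is the mean over subjects of
the two-visit SD over the two-visit mean (0/0 := 0); ICC is ICC(3,1) —
two-way mixed, consistency, single measurement, from the ANOVA mean
squares $({\rm MSR}-{\rm MSE})/({\rm MSR}+(k-1){\rm MSE})$; SEm is the
pooled SD times $\sqrt{1-{\rm ICC}}$. Identical visits with zero
between-subject variance are reported as CV 0, SEm 0, ICC 1.0 and flagged
(the degenerate perfect-agreement case, as arises for pre-exercise
soreness scores that are uniformly zero). The repeated-measures ANOVA is
the classical within-subject F with sphericity assumed; with two
timepoints it reduces exactly to the squared paired t. All tests are
two-tailed at alpha 0.05 with no multiplicity correction. Paired power
uses the noncentral t distribution with noncentrality $d_z\sqrt{n}$.

# The synthetic generator

The generator stands in for a laboratory capture. Its contract: given a
condition prescription — IC angles, landing-phase peak angles, landing and
propulsion durations, jump height, 0.30 m drop height — produce marker and
force files such that the full analysis pipeline recovers the prescription.

**Trajectory construction.** Each joint angle is piecewise quintic in
time and C2-continuous across the whole trial: a pre-contact preparation
segment (0.25 s, legs pre-shaping during the fall), the landing segment,
the propulsion segment, and constant-pose segments elsewhere. The foot
(ankle root) decelerates to rest over a 60 ms touchdown window ending
exactly at IC. Joint angles cross IC with nonzero angular velocity —
1.6–2.5× the mean landing rate per joint — so that the centre of mass
arrives descending and only decelerates during absorption, which is what
keeps the implied GRF positive; a rest-to-rest landing spline (zero
angular velocity at IC) would require the CoM to accelerate downward
first and implies a sustained negative GRF for the tabulated landing
durations, i.e. it is dynamically infeasible. The hip carries a larger
velocity share than the knee because their difference drives the shank
rotation rate, and a quiet shank at impact minimizes the
angular-acceleration content near the filter cutoff. At peak flexion
every angle reverses with a definite negative curvature (scaled
−2000 deg/s² for the largest-excursion joint): a flat peak would let the
filter's residual passband ripple move the detected peak instant by
several frames, a definite reversal pins it.

**Dynamic consistency.** Marker positions follow by forward kinematics;
the whole-body CoM follows from the markers plus the anthropometric
masses (the same body model the inverse dynamics uses); and the total
vertical GRF during contact is *derived* as $F = m\,(g + \ddot y_{com})$,
split equally between the plates, zero in flight. Impulse–momentum
closure over the contact therefore holds by construction and is asserted
by the tests as an invariant. Two scalar shaping conditions keep the
force morphology clean: the joint angular accelerations at IC are solved
(hip and knee, minimum intervention) so the CoM deceleration is zero at
the IC sample and positive after, and the take-off angular accelerations
are solved so the implied force approaches ~30 N at TO instead of
stepping down from hundreds of newtons. Infeasible prescriptions — a
knee trajectory that would overshoot its prescribed peak, or an implied
GRF negative for more than 50 ms — are rejected with a diagnostic naming
the constraint.

**Take-off and flight.** The take-off pose is deliberately flexed (knee
45°, hip 25°): with an ankle-rooted flat-foot chain (no heel rise
modelled), the pelvis can only reach its ballistic speed if the knee
still has extension range at TO. Joint velocities at TO are scaled so the
pelvis-centroid vertical velocity equals $\sqrt{2g\,\Delta h}$ with
$\Delta h$ the gap from the TO pelvis height to standing height plus the
prescribed jump height; the post-TO flight translates the TO pose
ballistically, so the pelvis apex equals standing height plus jump height
exactly.

**Noise.** Marker noise is i.i.d. Gaussian per frame and coordinate
(default SD 0.5 mm, typical optical-capture noise), force noise i.i.d.
Gaussian per sample (default SD 2 N), both seeded from the single root
seed; identical seeds reproduce trials bitwise.

**What the generator does not emulate.** The impact transient: a real
landing arrives with the CoM at ~2.43 m/s (a 0.30 m drop) and sheds that
momentum partly through heel-pad/shoe compression and segment wobble in
the first ~30 ms — content far above 15 Hz that a rigid planar chain
honouring the tabulated joint excursions cannot represent (matching the
impact speed through joint motion alone would overshoot the prescribed
peak angles). The generator instead pre-shapes the touchdown so its
kinematics resemble what a 15 Hz-filtered capture of the real event looks
like; the cost is that per-plate GRF peaks (~1.5–3 BW, emerging from the
dynamics) sit below typical raw-capture values, and the pre-contact
instants are not strictly force-free in a Newtonian sense. Heel rise
during propulsion, arm swing, frontal/transverse-plane motion and
bilateral asymmetry are likewise not modelled. Passing the
prescription-recovery tests therefore demonstrates the pipeline's
correctness on band-limited, dynamically consistent input — not its
robustness to raw impact artefacts in real captures.

# Cohort simulation and power

`run_study()` generates a pre/post cohort through the full pipeline:
each subject gets session-level condition parameters drawn around the two
sessions' group means with the tabulated between-subject SDs and a
shared-subject correlation across sessions (default 0.8, chosen a priori
as typical session-to-session repeatability of landing biomechanics; it
implies paired effect sizes near 1.05 for peak knee flexion, matching the
a-priori effect sizes such study designs assume). Draws that are
kinematically or dynamically infeasible are redrawn — only "successful
trials" enter the analysis, mirroring laboratory practice. Trials within
a subject and session differ only by measurement noise and are averaged
(three per session by default) before paired testing.

`simulate_study_power()` is the metric-level counterpart: it samples
subject metric values directly from the same bivariate model and reports
per-variable paired-t rejection rates. The study-level power claims are
computed this way (100 replicate studies of 13 subjects in seconds); the
full mocap pipeline is exercised end to end once per test run rather than
per replicate, a problem-size choice that keeps the suite at desk scale
while the metric-level and trial-level routes are tied together by the
prescription-recovery tests.

With 13 subjects and correlation 0.8, the design detects the tabulated
session effects with power ≳ 0.94 for peak knee flexion and ≥ 0.99 for
the phase durations — consistent with the study design's a-priori
calculation (dz = 1.05, alpha 0.05 two-tailed, power 0.8 at n ≈ 10–12;
the exact paired computation gives n = 10, a known conservatism of such
a-priori calculators).

# Numerical choices and degenerate inputs

- Sample indices are 1-based (R convention) and times are in seconds
  (`t = (i-1)/rate`); intervals are half-open `[start, end)`.
- Contact starts on an exact kinematic frame by construction in the
  generator, so the force-rate IC maps to a kinematic frame without
  interpolation; durations detected on noise-free trials are within one
  force sample of the prescription.
- Filter edge padding is odd reflection over `3 * ceil(rate/cutoff)`
  samples; series shorter than three times the filter order are rejected.
- Derivatives are central differences (exact for quadratics), one-sided
  at the series edges; inverse dynamics trims nothing, so its first and
  last two frames inherit one-sided-difference error — all analyzed
  events sit far from the trial edges.
- Ties in peak search resolve to the earliest frame. Zero knee range of
  motion makes stiffness undefined and is an error, not NaN. Marker
  dropouts up to 10 frames are cubic-spline filled; longer gaps are
  errors. A subject mean of zero with nonzero variability makes that
  subject's CV undefined and is reported as an error with a diagnostic.
- The ICC(3,1) point estimator carries a small finite-sample downward
  bias (about 0.01 at n = 20); parameter-recovery tests therefore check
  that the estimator distribution covers the variance-ratio truth and
  that its mean recovers it to within 0.02, rather than demanding exact
  mean-unbiasedness.

# Known limitations

Planar sagittal mechanics only; no frontal-plane projection angles, knee
abduction moments or tibial rotation. The anthropometric tables are
population averages for adult males and the bundled head-arms-trunk
"segment" is a single lumped mass above the pelvis. GRF magnitudes from
the generator are morphology-correct but not magnitude-calibrated to raw
captures (see above). The reliability layer implements two-visit designs;
more visits are handled by the ANOVA machinery but the CV definition is
two-visit. Real-capture ingestion expects the TRC dialect and the
package's force CSV; C3D import is out of scope.
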