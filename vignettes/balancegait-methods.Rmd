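---
title: "Methods: visually induced balance responses during treadmill walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visually induced balance responses during treadmill walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balancegait)
```

## The scientific problem

When a walking person perceives a sideways fall — here induced purely
visually, by rolling a virtual scene about the anterior-posterior axis —
the nervous system deploys a sequence of corrective mechanisms tied to the
gait cycle: a *lateral ankle* response (stance-ankle in-/eversion shifting
the centre of pressure, CoP, toward the perceived fall), a *foot placement*
response (the next footfall lands shifted toward the perceived fall), and
modulation of the trailing-leg *push-off*. `balancegait` implements the
full measurement chain for such experiments: stimulus generation and
scheduling, gait-event detection from marker kinematics, preprocessing,
step-normalized response extraction, outcome statistics, and — because the
original multi-subject recordings are not shipped with the package — a
synthetic walker with known ground truth against which every stage is
validated by parameter recovery.

## Stimulus protocol

The visual stimulus rolls the scene with constant angular acceleration of
60 deg/s² for 600 ms (reaching ½·60·0.6² = 10.8 deg), holds the angle for
2000 ms, and returns to neutral at constant velocity over 1000 ms
(`rotation_profile()`). Stimuli are triggered on heelstrikes; after each
reset to neutral, a washout of 10–13 heelstrikes (uniform, both feet
counted) elapses, and the next qualifying heelstrike triggers the next
stimulus with a uniformly drawn roll direction (`schedule_stimuli()`). The
online trigger threshold is the quiet-standing heel-marker height plus 3 mm
(`standing_trigger_threshold()`). Counting both feet in the washout is an
interpretation — the protocol description says "steps" without
qualification — and is flagged here as an assumption; the alternative
(trigger-foot-only counting) would roughly double the washout duration but
changes nothing downstream.

## The processing chain and its parameters

* **Filtering** (`lowpass()`): 4th-order Butterworth, applied
  forward–backward so that no phase lag distorts event timing, with
  odd-reflection padding that outlasts the filter's settling time. Cutoffs:
  10 Hz for kinematics, 50 Hz for force-plate data, 6 Hz for rectified EMG.
  All cutoffs are arguments, not constants.
* **Gap filling** (`fill_gaps()`): marker occlusions up to 100 ms are
  bridged by cubic splines through the flanking samples; longer runs are
  left missing and any step overlapping them is excluded rather than
  repaired.
* **CoM** (`compute_com()`, `com_state()`): the whole-body centre of mass
  is the mass-fraction-weighted mean of segment CoM positions over a
  compact five-segment table (trunk 0.532, pelvis 0.142, head 0.081, each
  leg 0.1225). A full anthropometric segment model and inverse kinematics
  are deliberately out of scope: the synthetic walker emits segment proxies
  for exactly these five segments, so generator and analysis share one
  convention and recovery tests are exact. Velocity and acceleration are
  central differences of the filtered position; the derivative scheme is
  not prescribed by the protocol text, and central differences at 250 Hz
  contribute relative errors below 3·10⁻⁴ at gait frequencies.
* **CoP** (`compute_cop()`): whole-body lateral CoP is total plate moment
  over total vertical force in the common (treadmill) frame. This is
  algebraically identical to the vertical-force-weighted combination of
  per-plate CoPs but never divides by a small per-plate force; a hard
  per-plate load threshold would otherwise toggle under sensor noise at
  every weight transfer and inject single-sample glitches precisely where
  the onset estimator differentiates the signal. The validity threshold
  (default 50 N) only flags samples with nobody on the plates.
* **EMG** (`emg_envelope()`, `emg_normalize()`): rectification, 6 Hz
  low-pass, then normalization so that the grand mean over all control
  strides is 100% per subject and channel.

## Steps, baselines and outcomes

A *step* runs from one heelstrike to the contralateral heelstrike.
Heelstrikes are prominent minima of the filtered vertical heel-marker
position (topographic prominence > 20 mm, per-foot spacing ≥ 250 ms, ties
resolved by keeping the more prominent peak); pushoffs are the first
subsequent peak of the 2nd-metatarsal vertical velocity with prominence
> 350 mm/s (`detect_gait_events()`). Event times are sample-resolved; at
250 Hz that is 4 ms, finer than any reported onset precision. Manual
corrections are applied through a reviewable edit table
(`review_events()`) and re-validated, never silently.

Each stimulus contributes steps −2, −1 (controls) and +1…+4; all
trajectories are resampled to 100 points per step (`normalize_time()`).
Combining trigger foot and roll direction under body symmetry yields
*toward*/*away* conditions; for left-foot triggers all lateral signals are
negated so that positive always means "toward the triggering foot"
(`classify_direction()`, `mirror_lateral()`). Responses are stimulus
trajectories minus the mean control trajectory of the same stance foot
(`baseline_subtract()`).

Foot placement (swing heel relative to stance heel at landing) is modelled
per subject as a linear function of the lateral CoM position and velocity
at *midstance*, fitted on control steps only (`fit_foot_placement_model()`).
Midstance is operationalized as 50% of normalized step time — the protocol
text never defines it, so the fraction is a prominent, configurable
argument (`midstance_frac`). The *stimulus-induced foot placement change*
is the observed placement minus the model prediction
(`stimulus_induced_fp_change()`); on control steps it is zero-mean by
construction of the least squares fit.

`compute_outcomes()` produces the seven step-+1 outcome variables: foot
placement change (mm), stimulus-induced foot placement change (mm), hip
abduction change of the swing leg at heelstrike (deg), integrated swing-leg
gluteus medius EMG change (%·s), integrated CoP-relative-to-CoM change
(mm·s), stance-ankle eversion change at heelstrike (deg), and integrated
stance-leg peroneus longus EMG change (%·s). Integrals run in real time
over the first post-stimulus swing phase, taken as the interval from the
swing-foot pushoff to the step-ending heelstrike. Spatial outcomes are
inverted for *away* stimuli and body-relative outcomes for *toward*
stimuli, so a stereotyped response has one sign in both conditions.

## Onset estimation

`estimate_onset()` follows the tangent-extrapolation scheme: pointwise 95%
CI of the pooled mean response; the contiguous region where the CI excludes
zero; the first local maximum of the response's rate of change; a tangent
line at that point; the onset is the tangent's zero crossing. Three
operationalizations matter when the pooled sample is small (a single
trial's worth of ~9 repeats rather than the thousands the scheme was
designed for), and all three reduce to the textbook rule as n grows:

1. each response is re-referenced to its own mean over the first 15% of
   step time — a window that precedes the earliest physiological response —
   removing step-level placement offsets that do not average out at small n;
2. the re-referenced window is excluded from the region search (it is
   uninformative by construction), and if several disjoint regions survive,
   the one containing the largest absolute mean response is analyzed;
3. the rate-of-change search extends backward from the region start to the
   last zero crossing of the mean, because at small n the exclusion region
   begins only after the rising flank that produced it; derivative maxima
   below half the window's peak rate are treated as baseline noise.

On a smoothstep of ramp duration *R* the tangent construction has a known
analytic offset of +*R*/6 (tangent at the half-way point, slope 1.5·gain/R):
with the generator's 60 ms ramps that is +10 ms, visible in the recovery
results below. Per-trial onset estimates are reported but underpowered by
design; study-level onsets pool the step +1 responses of all trials
(`run_recovery_study()`), mirroring the pooled-steps analysis of real
experiments.

## Inference

`fit_outcome_lmm()` fits `outcome ~ trigger_foot * direction +
(1 | subject)` by REML with sum-to-zero contrasts; `anova_fixed()` reports
Type-III F tests with Satterthwaite denominator degrees of freedom;
`lsmeans_ci()` reports least-squares means with Kenward-Roger 95% CIs
(Satterthwaite when pbkrtest is unavailable, recorded in the result's
`df_method` attribute — in balanced designs the two agree closely, which
the tests verify against the classical t-interval). Significance is "the
95% CI excludes zero"; p-values are reported but de-emphasized. Power
analysis is simulation-based (`power_simulation()`,
`power_required_n()`): outcomes are simulated from the random-intercept
model at a stated effect size, refitted, and tested by the same CI
criterion; the default 100 simulations per design matches common practice
for mixed-model power studies.

## The synthetic walker

`generate_trial()` prescribes trajectories kinematically — the package's
claims concern the analysis chain, so simulating dynamics would add realism
without adding testability. At the default 90 steps/min cadence it emits:

* heel and forefoot markers whose vertical trajectories have minima exactly
  at the true heelstrikes (raised-cosine strides, 80/100 mm lifts over a
  30 mm stance height) and whose first post-heelstrike velocity peak
  defines the true pushoff;
* a lateral CoM built per step from a half-sine toward the stance side
  (amplitude 20 ± 4 mm step-to-step) plus a second harmonic (SD 3 mm) that
  decouples midstance velocity from midstance position, so the placement
  regression is identifiable;
* foot placements following the linear law exactly in the mirrored frame:
  placement = −step_width + 0.4·(CoM position deviation) + 0.15·(CoM
  velocity) − 0.3·(feet-midline excursion) + stimulus offset + 2 mm noise.
  The third term is *station keeping*: without an absolute position
  feedback a relative placement law makes the feet a random walk, whereas
  real treadmill walkers hold their lane using vision and belt edges. The
  term is independent of the current CoM state, so the two-coefficient
  model the pipeline fits remains exactly recoverable (verified to machine
  precision on noise-free data);
* dual-plate forces whose moments encode the CoP under the stance foot with
  a 20%-of-step weight transfer, EMG envelopes as stride-locked Gaussian
  bursts on a 137 Hz carrier, and joint-angle channels;
* stimulus-locked injections with configurable onsets and gains: a CoP
  shift (default 8 mm at 300 ms), a foot-placement offset (5 mm at 420 ms,
  matching the effect size used in the power analysis), ankle/hip angle
  modulations (1–2 deg) and EMG amplitude modulation (30%), all entering as
  60 ms smoothsteps and decaying over step +2; spatial injections are
  signed by the perceived fall direction, body-relative ones by the
  toward/away condition;
* marker dropouts as contiguous gaps (0.01 per channel-second, geometric
  lengths with mean 60 ms, occasionally exceeding the 100 ms fill limit so
  the exclusion rule is exercised) and white measurement noise (0.5 mm
  markers, 2 N / 0.3 N·m plates, 0.05 a.u. EMG).

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify on real data — includes soft-tissue marker
artefacts, non-stationary cadence and asymmetric gait, EMG crosstalk and
baseline wander, correlated plate noise, and any mechanical coupling
between the injected responses (each response channel is injected
independently, whereas in a real walker the CoP shift, ankle torque and
placement are consequences of one another).

## Numerical choices and degenerate inputs

Step windows are selected by nearest-sample index arithmetic, not by
floating-point time comparisons, so boundary ties cannot shift a window by
one sample. Conflicting heelstrike candidates within 250 ms are resolved by
prominence; a plateaued peak counts at its first sample. Steps shorter than
50 ms, steps overlapping unfilled occlusions, and stimuli that cannot be
matched to a detected heelstrike within 10 ms are dropped with explicit
reasons, never repaired. An all-missing channel, a missing on-disk stream,
a zero control-stride EMG mean, a rank-deficient placement design and a
constant outcome all raise errors naming the problem. A singular subject
variance is reported with a warning but the fit is kept, since the grand
mean remains estimable.

## Problem sizes used in the validation suite

The test suite and the acceptance script validate recovery on 50 trials of
160 steps (about 107 s of walking and 9 stimuli each), calibration of the
direction test on 500 simulated null outcome tables (10 subjects × 2 × 2
cells × 4 repeats), and CI coverage on 150 tables with a direction effect.
These sizes were chosen so the whole validation runs comfortably on a
laptop while the binomial error of the calibration checks stays a small
fraction of the tolerances tested.

## Known limitations

* The walker is kinematic; its ground-truth "responses" are injected
  signals, not consequences of balance mechanics.
* Joint angles come from the generator (or an external inverse-kinematics
  stage); the package does not compute angles from markers.
* Onset estimation at a single trial's scale is noisy for the 5 mm foot
  placement effect (effect equals the step-to-step placement SD); pooled
  estimation is the supported regime.
* C3D import is not provided; the canonical interchange format is the
  delimited-table + YAML layout written by `write_trial()`.
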