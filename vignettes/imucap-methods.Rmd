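---
title: "Estimating motor capacity from body-worn inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating motor capacity from body-worn inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imucap)
```

## The problem

Children undergoing neuro-rehabilitation are assessed weekly by movement
scientists who watch them perform standardized tasks — turning cards,
picking up small objects, stacking dominos, the nine-hole peg test, a
timed-up-and-go (TUG) walk or wheelchair run, climbing stairs — and rate
each task on a 1–4 attribute rubric. The ratings are informative but
expensive (about 85 minutes of expert time per session). `imucap`
implements an automatic alternative: body-worn inertial measurement units
(IMUs — 3-axis accelerometer plus 3-axis gyroscope, sampled at 100 Hz) at
the wrists, hip and feet record every task; orientation-robust signal
features summarize each task execution; and a per-task linear model maps
the features onto the experts' normalized rating, evaluated by
leave-one-session-out cross-validation.

Because no recording of this kind is publicly deposited, the package
carries a synthetic-session generator that reproduces the statistical
structure the analysis relies on, with complete ground truth. Every stage
of the pipeline is tested against that ground truth.

## Signal model and preprocessing

All analysis operates on the Euclidean magnitudes of the acceleration and
angular-velocity 3-vectors, never on individual axes. Magnitudes are
invariant to any fixed rotation of the sensor, which buys robustness
against sensor displacement between (and within) sessions; the package
verifies this invariance property in its test suite with random rotations.

Axes are low-pass filtered before the magnitude is taken
(`lowpass_trace()`): a 4th-order Butterworth at 45 Hz, applied forward and
backward so that it is zero-phase and does not shift detected event times.
At 100 Hz sampling, 45 Hz sits just below Nyquist, so the filter is mainly
a noise guard; we use odd-reflection padding sized to the filter's
transient decay so that edges are clean and a constant series passes
through exactly.

Task boundaries come from a dedicated labeling sensor: the experiment
leader marks each task start with one fast rotation and each end with a
fast double rotation. `detect_task_boundaries()` finds supra-threshold
bursts on the labeler's x-gyroscope, groups bursts closer than 1 s into
events, and reads one-burst events as starts, two-burst events as ends.
Thresholds are not stated by the method's description, so they are package
choices: a median + 6·MAD gate decides whether any bursts exist at all,
and the working threshold is 30 % of the strongest burst — a long
quiescent recording then cannot produce spurious label events from noise
tails alone. The synchronization clap that opens each recording is found
by `detect_sync_clap()` as the largest above-threshold transient.

## The feature set

Seven magnitude features are computed per task (per wrist for bimanual
tasks; from the hip for locomotion):

* **TIME** (s) — task completion time, from `movement_interval()`
  (below).
* **MI** (g) — mean of the instantaneous acceleration magnitude.
* **MIV** (g) — RMS deviation of the magnitude about its task mean
  (population divisor): the spread of the acceleration histogram.
* **DF** (Hz) — the highest-energy bin of the DC-removed FFT energy
  spectrum; ties break toward the lower frequency.
* **SM** (dimensionless, in [0, 1]) — fraction of the spectral energy
  within a fixed 0.2 Hz band centred on DF. A fixed band in Hz (rather
  than a fixed number of bins) keeps SM comparable across task durations,
  whose spectral resolutions differ.
* **ARE** ((deg/s)²) — mean squared angular-velocity magnitude.
* **RANG** (deg/s) — max − min of the angular-velocity magnitude.

Locomotion tasks add step/stance features (walking: feet sensors; stairs:
upper-leg sensors): per-foot step duration (consecutive heel strikes of
the same foot), stance duration (heel strike to lift-off), their pooled
averages and right/left ratios. The wheelchair TUG adds **ArmSync**, the
push-cycle lag between the two wrists' acceleration peaks normalized by
cycle duration, computed over straight-driving only.

Feature-vector layouts are fixed per task class: 7 (single-handed, from
the performing wrist), 14 (bimanual — left block then right block; the
blocks are ordered by body side, not by affectedness, since affectedness
is metadata rather than signal), 11 (TUG walk and stairs: 7 hip + 4 gait),
8 (wheelchair TUG: 7 hip + ArmSync).

### Decisions the description leaves open

* **DC removal before the FFT.** Without it, gravity forces DF = 0 for
  every trace; DF is meant to be a movement rate, so the mean is removed
  for DF and SM, and total energy is the positive-frequency, DC-excluded
  energy.
* **SM band membership.** A bin belongs to the ±0.1 Hz band when its own
  frequency interval (centre ± half the resolution) overlaps the band.
  A tone that falls between two bin centres splits its energy across
  both; interval-overlap membership keeps both halves, where a naive
  centre-distance rule would drop one of them and make SM depend
  erratically on the task duration. Series shorter than 5 s cannot
  resolve 0.2 Hz; the band then collapses to the DF bin and the result is
  flagged (`band_limited`).
* **"Rotation energy".** No formula is printed for ARE; we use the mean
  squared angular-velocity magnitude, which has interpretable units and a
  trivially verifiable naive-loop oracle.
* **ArmSync phases.** The forward-push lag is the reported feature; the
  backward-release lag, discussed qualitatively as less synchronous, is
  returned as a diagnostic (`armsync_release`).

## Task-time detection

`movement_interval()` follows the sliding-window idea: the standard
deviation of the acceleration magnitude over a 0.5 s window advancing by
0.01 s, thresholded to find when the hand is moving. Two refinements make
the estimate accurate to a few hundredths of a second on synthetic ground
truth, where the naive reading of the procedure is biased by a large
fraction of the window length:

1. **Windowed power about the quiescent baseline.** The variance within a
   0.5 s window, computed about the *window's own mean*, discards most of
   the energy of movement cycles slower than the window (the window mean
   tracks the slow cycle), which distorts the rise of the activity
   profile at movement edges. We instead use the windowed mean of
   squared deviations from the global quiescent baseline (the magnitude
   median — quiescent and cyclic-active segments share a ~1 g mean).
   This quantity rises *linearly* in the window's overlap with the active
   region.
2. **Midpoint threshold, centre-of-window timing.** With a threshold
   midway between the quiescent and active power levels, the crossing
   occurs when the window is exactly half filled with movement, so the
   *centre* of the first/last supra-threshold window estimates the
   movement edge without bias, independent of movement amplitude. The two
   levels are estimated as eroded class means (transition samples are
   excluded — on short bursts they drag the level estimates toward each
   other and bias the boundaries outward), and the crossing is refined by
   linear interpolation. The power profile is smoothed over half a cycle
   period (estimated from the spectral peak with parabolic
   interpolation), which averages away the power ripple of cyclic
   movement.

An absolute threshold (in g) can be supplied instead of the adaptive
rule. A series whose active level is indistinguishable from its noise
floor (below 3× in std) is reported as "no movement" (`moved = FALSE`,
`time_s = NA`) — distinct from a zero-length movement. When a labeled
segment is active throughout (locomotion segments begin and end
mid-activity), feature extraction uses the segment duration as TIME.

## Wheelchair segmentation

Straight driving and turning are separated with SWAB (sliding window and
bottom-up) piecewise-linear segmentation. `bottom_up_breakpoints()` merges
adjacent segments while the merged least-squares line keeps its residual
below `max_error`; `swab_breakpoints()` runs the same merge in an online
buffer and reduces exactly to bottom-up when the buffer spans the series
(a tested equivalence). `segment_drive_phases()` applies SWAB not to the
raw magnitude but to a 10 Hz moving-RMS *activity envelope* (1 s window):
propulsion keeps the envelope high — the window always contains a push or
release peak — while coasting through the turn drops it. Segments are
labeled by mean activity with a two-level midpoint rule, adjacent
same-label segments merge into regime blocks, and each block boundary is
snapped to the nearest crossing of the envelope through the mid-activity
threshold (SWAB places a breakpoint somewhere on the activity ramp; the
crossing pins it down). A flat series yields a single "straight" block.

## The capacity model

For each task class, the normalized expert rating \(t \in [0,1]\) is
modelled as a linear function of the features,
\(y(\mathbf x, \mathbf w) = w_0 + \sum_j w_j x_j\), fitted by ordinary
least squares on min-max-standardized features (bounds learned on
training data only; unseen data may scale outside [0, 1], which is
allowed and flagged by the scaler's contract). To limit over-fitting at
the study's small sample sizes, only significant features are kept: each
weight's null hypothesis \(w_j = 0\) is tested with the standard OLS
coefficient t-test and features with \(p \ge 0.05\) are dropped in one
pass, followed by a single refit.

Evaluation is leave-one-session-out: folds are (subject, week)
assessments; left- and right-hand instances of single-handed tasks share
a fold and one model. By default scaling and the significance gate are
recomputed inside each training fold (leak-free). `paper_mode = TRUE`
instead gates once on the full dataset and only refits weights per fold —
useful when a single feature set per task is wanted for reporting. Targets are not rescaled per fold: they
arrive normalized, and because OLS predictions are affine-invariant in
the target, a per-fold min-max of \(t\) followed by the inverse map would
return bit-identical predictions.

When a training fold has fewer rows than features + 2 (possible for the
14-feature bimanual layout at small cohorts), a marginal pre-screen keeps
the features with the smallest univariate no-correlation p-values, up to
rows − 3, before the joint fit; the joint gate then prunes further.

Prediction quality is reported as RMSE on the [0, 1] rating scale plus
the Pearson correlation with its no-correlation p-value. A fold whose
gate drops everything predicts the training mean (flagged
`intercept_only`); zero-variance predictions make the correlation
undefined, which is reported as an explicit `degenerate` flag rather than
a silent `NaN`. With two prediction pairs the correlation is computed but
its test has no degrees of freedom, so the p-value is `NA`.

`pooled_generalization()` implements the task-independent view: SM, ARE
and RANG averaged over all single-handed task instances per (subject,
week) with the summed rating — TIME and DF are excluded because they
depend strongly on which task was performed. On synthetic cohorts the
pooled cloud separates cleanly by impairment level in all three
coordinates.

## The synthetic study

`simulate_session()` builds full multi-sensor recordings: per-task
signals embedded in a quiescent gravity-plus-noise background, 2.5 s gaps
between tasks, and a labeling trace with the start/end rotation bursts.
The default cohort (`simulate_cohort()`) is 4 subjects × 4 weeks — a
realistic pilot scale for weekly pediatric assessments — with week-1 impairment levels spread over [0.2, 0.8], alternating
affected sides, and a 0.05-per-week recovery trend.

The manual-task signal is a sinusoid at the task's cycle rate (about
0.8–1.4 Hz depending on the task) riding on gravity, plus broadband
noise. Rising impairment level lengthens the active window (level 1 takes
twice as long as level 0), shrinks the tone amplitude (0.35 g → 0.09 g)
and the gyroscope amplitude (180 deg/s → 54 deg/s), and raises the
in-task noise floor (0.03 g → 0.11 g) — so TIME increases while SM, MIV,
ARE and RANG all decrease, the directions the capacity features are
designed to resolve. The movement starts and stops at peak excursion (an
integer number of half-cycles, cosine phase): task boundaries are then
crisp energy edges, the property that makes ±0.06 s time recovery a
meaningful target. Trial-to-trial variability enters as independent
per-instance jitters (±15 % duration, ±10 % amplitude and rate), which
also makes the feature design full-rank so the generating weights are
identifiable.

Gait traces place a 30 ms half-sine impact transient (2 g over baseline)
at each programmed heel strike, a ~1 g plateau during stance, and an
elevated oscillation during swing. Wheelchair traces give each push cycle
a dominant push peak and a smaller release peak per wrist, the left wrist
lagging by a programmable fraction of the cycle, in a
straight–turn–straight layout whose breakpoints are ground truth.

Ratings are generated as a known affine function of the *extracted*
features plus Gaussian noise, clamped to [0, 1]:
\(t = \mathrm{clamp}(w_0 + \mathbf w^\top \mathbf f + \varepsilon)\).
Using the extracted features (computed at generation time and stored on
the instance) makes noiseless identifiability exact and testable: with
\(\varepsilon = 0\), leave-one-session-out recovers the generating
weights to numerical precision. The default generating weights put most
of the rating on TIME with smoothness and angular-velocity range as
secondary contributors — mirroring which features the capacity analysis
typically finds significant — and are scaled so ratings stay inside
(0.1, 0.95) and the clamp almost never binds. Weights are per task kind;
gait ratings are driven by step duration, wheelchair ratings by ArmSync.

### What the generator does not emulate

The simulator makes no attempt at biomechanically realistic limb
kinematics, sensor drift, magnetometer output, or the within-task
substructure of real manipulation (individual object pickups). Passing
recovery tests on this generator therefore demonstrates that the
estimators are correct for signals with the stated statistical structure
— crisp movement edges, impact transients, cyclic propulsion — not that
they are robust to every artifact of real pediatric recordings. The
small-sample behaviour, however, is faithful: with one instance per
session and 14 or 11 features, training folds of 15 rows are genuinely
under-determined, significance gating frequently collapses to
intercept-only models, and the resulting cross-validated correlations can
be poor or even exactly −1 (predicting the training mean of a held-out
single instance is an affine decreasing function of that instance's
target). The single-handed tasks, with twice the instances per session
(one per hand), are where the model is reliably identifiable.

## Numerical choices and degenerate inputs

* Intervals are half-open `[start, end)` in 0-based samples everywhere.
* Heel-strike defaults: 1.8 g strike threshold, 0.4 s refractory, 0.15 g
  swing threshold about the 1 g plateau, 0.1 s post-impact blanking; all
  exposed as arguments. No events is an empty result, not an error.
* DF ties break toward the lower frequency; `which.max` makes this
  deterministic.
* Constant training columns abort min-max scaling with the feature named;
  rank-deficient designs abort the fit naming the collinear columns.
* Text round trips (`write_session()` / `read_session()`) preserve
  doubles to ~15 significant digits; rows with non-finite values are
  rejected on read with their row index, never dropped.
* Every generator takes an explicit seed and restores the caller's RNG
  state; the pipeline is bit-reproducible given its config
  (`run_pipeline()` writes no timestamps).

## Problem sizes

The shipped tests and the acceptance script run the pipeline at the
study's own scale: 16 synthetic sessions (4 × 4) for the end-to-end demo,
20-seed Monte-Carlo batches for event-recovery checks, 10 replicate
cohorts for the noisy-regression check, and 1000 simulated fits (n = 30)
for the selection-calibration check. These sizes keep every Monte-Carlo
estimate stable at the tolerances asserted while the whole suite runs in
about a minute.
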