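---
title: "Saccade kinematics and calcium encoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saccade kinematics and calcium encoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

SaccadeFlow implements a two-stage analysis for tethered larval zebrafish
experiments in which horizontal eye position is tracked (60-300 Hz) during
two-photon calcium imaging (4.8 Hz frame scanning): a behavioural stage that
detects and classifies saccadic eye movements, and a neural stage that
identifies and characterizes oculomotor-tuned ROIs from their fluorescence
time series. This vignette explains the underlying models, the parameters
that matter, the synthetic-data generator used for validation, and the design
decisions taken where the procedure left genuine freedom.

## Sign conventions

All eye angles live in one head-fixed frame: positive = rightward rotation,
for both eyes. Nasal (adducting) direction is therefore positive for the left
eye and negative for the right eye. Vergence is `left - right`; positive
vergence means the eyes are converged. Convergent saccades move both eyes
nasally (left eye +, right eye -); conjugate saccades move both eyes with the
same sign.

## Saccade detection

Detection is deliberately two-resolution:

1. **Coarse (100 Hz)**: each eye trace is linearly resampled to 100 Hz,
   low-pass filtered at 1 Hz with a zero-phase 2nd-order Butterworth (zero
   phase preserves event timing), and convolved with a 160 ms antisymmetric
   step kernel. The convolution is rescaled by the chain's own step response
   so that its units are displacement degrees (the 1 Hz filter attenuates an
   instantaneous step to roughly 0.22 of its amplitude; without the rescaling
   a threshold "in degrees" would be misleading). Candidate events are local
   maxima of the rescaled magnitude above `threshold_deg` (default 1.5
   degrees) that additionally rise above the shallower of their flanking
   minima (within 0.75 s) by the same threshold. The prominence requirement
   exists because constant-velocity episodes — optokinetic slow phases,
   post-convergence divergence drifts — pass the 1 Hz filter unattenuated and
   otherwise turn the convolution into a noisy plateau full of spurious local
   maxima. Candidates within 0.5 s of the trace boundary are dropped.

2. **Pairing and refractory**: left- and right-eye candidates within 100 ms
   are greedily paired (nearest partner first) into binocular events; events
   beginning within 300 ms of the previous retained event are discarded,
   earliest event winning.

3. **Refined onset (500 Hz)**: the raw trace is resampled to 500 Hz and
   LOWESS-smoothed (80 ms span), except where the 160 ms step convolution
   exceeds 3 degrees — putative saccade samples are left unsmoothed so the
   saccadic velocity profile survives. The onset is the first time, within
   the 400 ms window centred on the coarse peak, at which the product of the
   100 ms and 40 ms step convolutions crosses 10% of the window maximum.
   Windows whose product never exceeds an absolute floor (0.25 deg^2,
   configurable) contain no saccade and the event is rejected; this is what
   removes the drift-edge candidates that survive the coarse stage.

A geometric caveat: for an idealized instantaneous step, the convolution
product rises from zero starting 20 ms before the step, so the 10% crossing
sits ~15-18 ms early. On saccades with a finite rise (the minimum-jerk
waveforms of the generator, or real saccades), the median onset error is
about 6 ms. A higher relative threshold would reduce the ideal-step bias but
delay onsets on real saccades; 10% is the default and both it and the
absolute floor are arguments.

## Event measures and the nine-metric descriptor

Per eye: pre-saccadic position (median over 200 ms before onset), max
post-saccadic position (largest absolute deviation from the position at onset
within 200 ms after onset), median post-saccadic position (median over 200 ms
from the max-post time), and cw/ccw velocity (max and min of the central
difference of the smoothed 500 Hz trace over a 150 ms window centred at
onset). Note that on a constant-velocity segment the cw and ccw extrema
coincide at the drift velocity — the minimum is not clipped at zero.

Each binocular event is summarized by nine metrics, in fixed order: amplitude
(L, R) = median-post minus pre; max-median amplitude (L, R); velocity (cw,
ccw x L, R); vergence = left minus right median post-saccadic position.
Metrics are normalized per animal by winsorizing at the [0.5, 99.5]
percentiles and z-scoring with the winsorized mean and SD; zero-variance
columns become all-zero and are flagged.

## Classification and lateralization

New events are classified by embedding their normalized nine-metric vectors
into a labeled two-dimensional reference space and taking the modal label of
the 100 nearest reference neighbours (ties broken by summed inverse
distance — deterministic). The reference space is fitted supervised on a
labeled synthetic metric set drawn from the kinematic model (300 points per
type by default); the projection is a linear discriminant basis (first two
discriminant axes). A `metric9` backend performs the same 100-NN vote
directly in the 9-D normalized space. The embedding separates convergent from
left/right conjugate saccades; the left/right lateralization of *convergent*
saccades is then assigned by the sign of post-saccadic version (the mean of
the two median post-saccadic positions), because version reflects absolute
gaze direction that amplitude geometry alone cannot carry when gaze is
eccentric. Exactly zero version falls back to a configurable default and is
flagged.

## Velocity main sequence

Peak velocity versus amplitude is fitted as `V = Vmax * (1 - exp(-A / A0))`
by Levenberg-Marquardt least squares, with a small grid restart on failure.
AIC uses the Gaussian form `n * log(RSS/n) + 2k` with `k = 2`. The
pooled-versus-type-specific comparison fits one pooled curve (k = 2) and two
type curves (joint k = 4) per eye and reports the per-eye AIC difference, the
across-eye fraction preferring the two-model fit, the mean two-model Akaike
weight (both statistics are reported because "percent AIC" summaries are
ambiguous), and a signed-rank p value on per-eye AIC differences. In the
saturation regime (A >> A0) the amplitude constant is weakly identified; the
fit still returns `Vmax ~ mean(V)` and flags non-convergence when the
optimizer fails outright.

## zF standardization

Frames whose motion error exceeds 5 um are replaced by linear interpolation
per ROI. The baseline is the 50th percentile of the trace; the noise scale is
the robust first-difference estimator `median(|diff(x)|) / (sqrt(2) *
qnorm(0.75))`, which is exact in expectation for white Gaussian noise and
insensitive to sparse calcium transients (a median-filter residual estimator
was evaluated and rejected: its expectation is biased low by ~35% on white
noise because a point that is its own window's median leaves zero residual).
zF = (F - baseline) / noise is invariant to affine rescaling of the raw
fluorescence; zero-noise ROIs are floored at machine epsilon and flagged.

## Saccade-triggered d' and the permutation null

For each ROI and saccade type (convergent pooled over lateralizations, left
and right conjugate separate), d' = (mu_post - mu_pre) / sqrt((var_post +
var_pre)/2), pooling every (event, frame) sample in a 2 s post window and a
1 s pre window. The null redraws the onset frames uniformly (event count
preserved) 1000 times; the ROI is active for a type when the observed d'
exceeds the null's 95th percentile. Because uniform redraws allow shuffled
windows to overlap while real events never do, the null is slightly wide at
high event density: on white-noise ROIs the measured type-I error is ~0.042
with 20 events per 600 s session and drifts down to ~0.024 with 70 events.
The test is therefore conservative, never anti-conservative, as event density
grows.

## The 33-regressor design

Six oculomotor predictors (four saccade-onset one-hots: convergent gaze-left,
convergent gaze-right, conjugate left, conjugate right; two rectified nasal
eye-position traces, the experiment-wide median subtracted and the temporal
side zeroed), eight locomotor predictors (swim onsets by direction x
per-session vigour quartile, quartiles assigned by rank so ties never break
the partition), and eighteen stimulus predictors (two grating-direction
block indicators; sixteen moving-spot one-hots = 4 azimuth bins spanning -60
to +60 degrees x 2 directions x 2 contrast polarities; the bin count is
chosen to satisfy the 18-stimulus-predictor total). All 32 are convolved with
the calcium impulse response function h(t) = (1 - exp(-t/tauOn)) *
exp(-t/tauOff), tauOn = 0.2 s, sampled at the frame rate on [0, 5*tauOff] and
normalized to unit maximum, then delayed by the frame offset. The motion-error
column is appended unconvolved. Column count is validated at 33 = 6 + 8 + 18
+ 1.

## Hyperparameter search, ridge and unique variance

The OLS search is exhaustive over tauOff in {3, 4, 5} s and offsets 0-3
frames (12 designs, shared across ROIs); ROIs pass to ridge only when the
best OLS R^2 exceeds 0.05. Ridge standardizes the columns, centres the
response, fits without intercept, and selects lambda from a 13-point log grid
(1e-3..1e3) by out-of-fold R^2 over 10 contiguous frame blocks — contiguous
folds limit leakage through temporal autocorrelation, which random folds
would hide. Per regressor, the column is circularly shifted by a seeded
random offset of at least 10 frames and the cross-validated fit is recomputed
at the same lambda and folds; delta cvR^2 = permuted minus original. The
refits reuse each fold's Gram matrix with a single-column update, so the full
33-regressor attribution costs little more than one fit. Collinear regressors
mask each other's unique contribution (each shows delta cvR^2 near zero); this
is a documented property of the method, not a defect of the implementation.

The tuned classification pools the positive delta cvR^2 values across ROIs as
the permutation null and requires (i) the most negative delta to belong to an
oculomotor regressor, (ii) at least one oculomotor delta below minus the
null's 95th percentile (signed comparison; the two-sided variant mirrors the
pooled positives about zero), and (iii) the motion-error delta to be less
negative than that bound. Type labels come from the d' flags; "Both" requires
convergent plus at least one conjugate activation.

One caveat on tauOff identifiability: at the generator's default
signal-to-noise (peak transient 2.5 zF units against unit noise) the R^2
separation between adjacent tauOff values is of order 1e-3, so single-ROI
recovery of tauOff is ~0.9 for a three-saccade-type cell and ~0.96 for a cell
responding to all four saccade types; the offset is recovered essentially
always. This is a property of how weakly the decay tail constrains an
event-train regression at 4.8 Hz, and it is why the search is run per ROI but
interpreted population-wise.

## Tuning metrics

*Normalized saccade-triggered fluorescence*: per saccade, zF minus its 1 s
pre-onset mean, summed over 2 s from onset, divided by the per-ROI 95th
percentile across saccades. *Rectilinear fits* regress these values on
normalized post-saccadic eye position with a horizontal baseline (median over
the span) plus a least-squares linear ramp beyond a threshold position,
scanning 41 evenly spaced breakpoints (the last candidate is baseline-only,
so the selected fit never has a larger MSE than the baseline alone); the ramp
is accepted only when its fitted excursion exceeds twice the RMSE of the
baseline-only fit (the acceptance rule is otherwise unquantified;
the multiple is an argument). *Saccade-type index*: each conjugate adducting
saccade of the assigned eye is matched to the closest convergent saccade
within Euclidean distance 0.1 in normalized (position, velocity) space —
matching is per conjugate event, convergent partners reusable (a
without-replacement variant is available); the index is the median
convergent-minus-conjugate difference over matched pairs, positive meaning a
stronger convergent response, NA when nothing matches. *OKR power*: the
median zF time course across leftward grating presentations minus the
rightward median, mirrored into one full alternation cycle and Fourier
transformed; the score is the power at the bin at 1/(2 x epoch duration). The
alternation frequency is inferred from the stimulus log's direction-switch
period. *PC1 score*: both metrics standardized across ROIs and projected on
the first principal component, sign oriented so the saccade-type index loads
positively (zero mean by construction). *Directionality preference* sums
delta cvR^2 over the leftward triple (conjugate-left onsets, convergent
gaze-left onsets, right-eye nasal position) and the rightward triple; the
more negative sum wins, ties default to leftward with a flag, and the
preferred direction routes the index and nasal ramp fits to the contralateral
eye.

## Perturbation metrics

Ablation deficits are per-eye, per-type differences of medians (post minus
pre epoch) of post-saccadic nasal position and nasal peak velocity, requiring
at least 5 saccades per cell, with both pooled and lateralization-split
outputs (the pooling convention is not uniquely determined, so both are
produced). The convergent-minus-conjugate residual is regressed on the median
saccade-type index of the manipulated cells by OLS (>= 4 animals), reporting
slope, R^2 and a two-sided slope p. Optogenetic position change is the median
over the 250 ms window ending at stimulus offset minus the median over the
250 ms window ending at onset, per eye, rejecting epochs shorter than 500 ms.

## The synthetic-data generator

The generator exists so every stage can be validated against known ground
truth. What it emulates:

* **Saccades** are minimum-jerk position steps; the waveform is a design
  choice (no waveform is prescribed by the procedure), picked because its
  peak velocity has the closed form (15/8) x amplitude / duration, letting the
  generator place each saccade exactly on its type's main sequence. Defaults:
  conjugate Vmax = 700 deg/s, A0 = 6 deg (saturating near 700 deg/s);
  convergent Vmax = 1800 deg/s, A0 = 25 deg (weak saturation, velocity keeps
  scaling with amplitude). A per-saccade +-12% main-sequence gain jitter
  models biological dispersion. Conjugate saccades retarget gaze within +-8
  degrees with a 4-degree minimum amplitude (small saccades sit below the
  3-degree smoothing guard and their velocities cannot be measured reliably,
  and spontaneous zebrafish saccades are typically >= 4-5 degrees).
  Convergent saccades draw a total vergence change of 13-17 degrees, split so
  the post-saccadic version sign fixes the lateralization, and are followed by
  a smooth 3 s divergence drift back to the pre-saccade positions; the
  schedule holds fixation until the drift completes, as fish rarely saccade
  mid-divergence.
* **Optokinetic blocks**: constant-velocity slow phases (6 deg/s) alternating
  direction every 4 s, with conjugate reset saccades whenever gaze would
  leave +-8 degrees.
* **Moving spots** sweep 152 degrees of frontal space at 30 deg/s and evoke a
  convergent saccade at a configurable latency (0.5 s) after a trigger
  azimuth drawn near the midline — no claim of fidelity to real response
  latencies is attached; the trigger-side sets the lateralization. Three spot
  trials per 60 s block give a hunting rate of ~3 events/min.
* **Swims** are Poisson bouts (0.08 Hz) plus bouts coupled to 40% of
  saccades, each with a direction and a lognormal vigour scalar (vigour has
  no agreed definition; quartiles are computed per session).
* **Motion error** wanders in 0-2 um, with Poisson-timed excursions of 6-10
  um (to exercise the > 5 um interpolation rule) and 2.5-4.5 um bumps coupled
  to 30% of saccades, so motion-artifact ROIs correlate with behaviour the
  way real residual motion does.
* **Fluorescence** is generated by inverting the encoding model: F = baseline
  + gain x (W X' + noise), where X is the session's design at the true CIRF
  (tauOff = 4 s) and offset (2 frames), columns normalized to unit peak so a
  weight reads as the ROI's peak response amplitude in zF units. ROI classes:
  `mrmn_both` (convergent + one conjugate type + ipsilateral nasal position),
  `mrmn_conv` (convergent only), `inn_like` and `lrmn_like` (one conjugate
  type + nasal position), `locomotor` (swim onsets), `motion_artifact`
  (follows the motion-error trace), `silent` (noise only). Default peak
  weights are 2.5 zF units for event responses against unit calcium noise —
  zF is noise-normalized by construction, so 1 is the only natural noise
  scale, and 2-3 noise-SD transients are a deliberately conservative level
  for clearly tuned cells.

What the generator does **not** emulate: raw imaging (no images or
segmentation), pupil/vertical/torsional eye movements, tail kinematics beyond
bout onset/direction/vigour, slow fluorescence drift or bleaching, spike
dynamics beyond the linear CIRF, response adaptation or history dependence,
and the anatomical topography of ROIs. Passing the suite therefore
demonstrates that the pipeline recovers what it is designed to recover under
its own generative assumptions — not that those assumptions exhaust real
recordings.

## Problem sizes and numerical choices

The validation suite uses one 600 s session (about 110 saccades, 56 ROIs: 8
per class) for the end-to-end checks; 200-saccade schedules for
detection/classification; 20-40 noise draws or seeds for the Monte-Carlo
properties (d' type-I error uses 20 seeds x 50 white-noise ROIs x 1000
shuffles against the session's ~20 convergent events); and 180 s
two-ROI-per-class sessions for bit-for-bit determinism. All randomness
derives from explicit integer seeds; reruns are byte-identical. Degenerate
inputs are handled explicitly: zero-variance metric columns (zeroed +
flagged), zero-noise ROIs (epsilon floor + flag), rank-deficient designs
(tiny-ridge fallback + flag), all-frames-bad motion (error), degenerate
position spreads in the rectilinear fit (baseline-only + flag), exact ties in
the modal vote (inverse-distance), lateralization (default + flag) and
directionality (leftward + flag).

## Known limitations

* tauOff is weakly identified per ROI at realistic SNR (see above).
* The uniform-shuffle d' null grows conservative with event density.
* The circular-permutation attribution cannot separate collinear regressors.
* The saccade-type index requires kinematic overlap between convergent and
  conjugate saccades of the assigned eye; sessions dominated by one gaze
  direction can yield few or no matched pairs for one eye (the index is then
  NA, mirroring real recordings where a fraction of ROIs is uncomputable).
* The 2-D discriminant embedding is linear; a nonlinear embedding could in
  principle separate types that the linear basis cannot, but the nine-metric
  geometry of the four types is close to linearly separable by construction.
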