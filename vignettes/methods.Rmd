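---
title: "Detecting falls, stumbles and comas from a waist-worn IMU: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting falls, stumbles and comas from a waist-worn IMU: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The detection problem

A worker wears a single inertial sensor near the waist.  It streams, at
10 Hz, three body-axis accelerations (in g), plus pitch and roll (degrees).
From that stream the system must decide, every time step, whether the
wearer is **safe** (0), has **fallen from height** (1), has **stumbled** at
ground level (2), or is in a **coma** — prolonged stillness after a
collapse (3).  The hard part is not the laboratory signature of a fall; it
is surviving a construction site, where walking on gravel, climbing
stairs, and riding a motorcycle over potholes all produce impact-like
accelerometer spikes, and sitting quietly at rest produces exactly the
low-variance stillness that characterises a coma.

Two detectors are implemented and compared:

* `her_s()` — a **hierarchical threshold** baseline.  Fixed rules over
  signal-vector-magnitude features, evaluated in a fixed order.
* `gru_s()` — a **gated recurrent unit (GRU) sequence classifier** over
  2 s sliding windows, trained by backpropagation through time.

## Features and windowing

The feature family is the signal-vector-magnitude (SVM) triple:

* `svma` \eqn{= \sqrt{a_x^2+a_y^2+a_z^2}} — about 1 g at rest, dips toward
  0 in free fall, spikes at ground impact;
* `delta_svma` — the first difference of `svma` between consecutive
  samples, large for abrupt movement (0 for the first sample of a
  recording, where no predecessor exists);
* `svmo` \eqn{= \sqrt{pitch^2+roll^2}} — posture magnitude.  No canonical
  formula exists for an orientation SVM; the Euclidean norm of the two
  available angles is this package's reading, and it is only ever used
  through configurable thresholds, so another monotone combination would
  calibrate to the same behaviour.

Classification operates on sliding windows of 20 samples (2 s) advanced
with stride 1, each labelled by the status of its **10th** sample (1-based
counting).  So a recording of 21 samples yields two windows: samples 1–20
labelled by sample 10, and samples 2–21 labelled by sample 11.  Windows
never straddle recording (participant) boundaries.  The per-time-step
channel set fed to the classifier is configurable and defaults to the
eight channels `(ax, ay, az, pitch, roll, svma, delta_svma, svmo)`; which
channels the original deployment used is not recorded anywhere, so the
default is simply "everything available".

## The synthetic-scenario simulator

The study data this package targets cannot be redistributed (destroyed
under the governing IRB consent), so the package ships a simulator whose
**defaults define the study conditions**: a session plan per participant
containing walking on even and uneven surfaces, stairs, a slope, 90 s of
gravel trail, motorcycle riding with speed bumps, two dropped falls, four
directional stumbles (forward/left/right/rear), one progressive and one
abrupt coma, and two minutes of seated rest — 542 s = 5,420 samples, i.e.
approximately the 5,500 samples per participant that the original
experiment's bookkeeping implies, and 30 participants give about 165,000
samples.  A five-participant test split carries 10 fall, 20 stumble and 10
coma target events.

Each scenario is an ordered list of phases; each phase draws an SVMa
magnitude series and posture targets:

* rest: 1 g with 0.02 g noise plus occasional small "fidget" impulses
  (1.1–1.4 g) every 4–12 s — resting people move slightly, which is what
  makes coma-vs-rest hard;
* walking: 1 g ± 0.3 g sinusoid at 2 Hz; uneven/gravel/slope add impulsive
  1.5–2.5 g spikes at 0.4–2 s spacing; stairs add periodic 1.8–2.2 g
  steps; motorcycle adds broadband vibration plus 2.5–3.5 g bumps;
* fall from height: sway, then free fall at 0.15 g for 0.3–0.8 s, then a
  4–6 g impact for 0.1–0.2 s, then lying stillness;
* stumble: a shallower 0.5 g dip, a 2–3.5 g impact and an unsteady
  recovery, with the stumble-labelled span lasting 2–3 s, followed by
  normal walking;
* comas: progressive (rest, sit-down transient, ≥30 s stillness at a
  slumped posture) and abrupt (standing, fall-like collapse, lying
  stillness).

Orientation follows an Ornstein–Uhlenbeck drift toward each phase's target
posture (upright ≈ 0°, lying ≈ 85° pitch); the acceleration vector points
along body-frame gravity with the phase's SVMa magnitude, plus small
per-axis noise.  Every magnitude above is an **engineering default chosen
once for separability and confusability**, not a measured value: the
overlap between stumble impacts (2–3.5 g) and motorcycle bumps (2.5–3.5 g)
is deliberate, because that overlap is the documented failure mode of
threshold detectors in the field.

Each simulated recording carries a machine-readable *phase plan* — the
ground truth of phase boundaries and labels — used by tests and event
evaluation, and writable as a JSON sidecar next to the CSV interchange
format.

What the simulator does **not** model: biomechanically realistic limb
dynamics, sensor bias/saturation, magnetometer or gyroscope rate channels,
and the messiness of real site work (tool use, bending, carrying).  A
detector that separates these synthetic classes has demonstrated the
intended signal-morphology reasoning, not field readiness.

## The hierarchical threshold baseline

The decision hierarchy, evaluated per sample, is: (1) **fall** — impact
evidence (`svma` above `theta_impact`, or vertical-axis |acceleration|
above `theta_vert`) preceded within 1.5 s by a dip below `theta_freefall`,
with a posture change above `posture_change`; (2) **stumble** — impact or
`delta_svma` evidence without the full fall signature; (3) **coma** —
rolling 2 s `svma` standard deviation below `stillness_sd` sustained for
at least `stillness_duration` (10 s default) while the smoothed posture is
non-upright (`svmo` above `lying_angle`); (4) safe.  Earlier rules shadow
later ones, so exactly one label is emitted per sample.

This hierarchy is a reconstruction: the benchmark system it stands for is
described in the literature only as combining SVM and vertical-
acceleration thresholds hierarchically, with its exact thresholds
unpublished.  Hence nothing is hard-coded: `her_s()` calibrates the
thresholds by exhaustive grid search maximising per-sample macro-F1 on
training data, with deterministic first-in-grid tie-breaking.  The posture
gate on the coma rule is this package's addition — without it, any worker
standing still for ten seconds would be declared comatose; the companion
`lying_angle` field (default 45°) was added to the threshold configuration
for that reason.  The rolling-statistics window for the stillness rule
defaults to 2 s, matching the decision granularity of the windowed system.

## The GRU classifier

Architecture: one GRU layer (64 units by default) consumes the window one
time step at a time; its final hidden state feeds five dense hidden layers
(128, 64, 32, 16, 8) with ReLU activations, dropout (rate 0.2) after dense
layers 1 and 3, and a softmax output over the four classes.  The five
dense hidden layers, two dropout layers, one output layer and ReLU hidden
activation are the documented shape of the original model; where the
recurrent computation sits relative to the dense stack is not documented,
and a single GRU layer in front is the natural reading for a model that is
called a GRU throughout.  The update equations are the standard ones
(update gate \eqn{z_t}, reset gate \eqn{r_t}, candidate \eqn{\tilde h_t},
\eqn{h_t=(1-z_t)\odot h_{t-1}+z_t\odot\tilde h_t}), giving
\eqn{3(U(U+C)+U)} recurrent parameters — checked in the tests against an
independently computed closed form.

Training: cross-entropy loss, Adam (learning rate \eqn{10^{-3}}), batch 64,
15 epochs by default, 10 % validation split, channels standardized with
training statistics stored on the model.  The GRU layer, backpropagation
through time and Adam are implemented in base R with batched BLAS matrix
operations — no deep-learning framework is a dependency — which trains the
cohort-scale model in a few minutes on one CPU.  Epoch count, widths,
optimizer settings and dropout placement are unrecorded in the source
study; the defaults here were chosen once as ordinary values for a model
of this size and are all configurable.  Every random draw (initialisation,
shuffling, dropout, validation split) is derived from the configuration
seed, so training is bit-reproducible on one platform.  Inverse-frequency
class weighting is available (`class_weights = TRUE`) for the strongly
safe-dominated label distribution but is off by default, matching the
plain training the original description implies; on the default synthetic
cohort plain training already learns the rare classes.

## Two-level evaluation

Per **time unit**: the 4×4 confusion matrix, and one-vs-rest accuracy,
precision, recall, specificity and F1 per class, reported at 2 decimal
places (percentages) and 3 (F1).  A metric with a zero denominator is
reported as 0.  Alarm-centric `alarm_rates()` (correct/incorrect alarms
over alarms generated) deliberately ignore the dominant safe class; with
zero alarms they raise a typed error rather than reporting 0, because "no
alarms" and "all alarms wrong" must not be conflated.

Per **event**: maximal runs of identical non-safe labels become alarm
events; same-type runs separated by at most 2 s of safe merge.  A truth
event counts as accurately detected iff at least one not-yet-used alarm of
the same type overlaps it within a ±2 s tolerance; matching is greedy in
time order and one-to-one; unmatched alarms are false alarms of their own
type.  A truth event covered only by an alarm of the wrong type (a fall
flagged as a stumble, say) is a miss *and* a false alarm, and such pairs
are tallied separately.  No published description of the original event
matching exists; the greedy ±2 s rule is this package's
operationalisation, with both the tolerance and merge gap configurable,
and the tests verify that on realistic (non-nested) event sets greedy
matching attains the exhaustive-matching optimum.

`coma_persistence_filter()` implements the long-horizon decision rule for
coma-vs-rest: confirm a coma label only when at least a configurable
fraction (default all) of the trailing 30 labels are coma, since a
resting person flickers back to safe occasionally while a genuinely
comatose one does not.  Labels with less than a full trailing horizon are
treated conservatively (missing history counts as non-coma).  The filter
can only demote labels, so it never increases coma false alarms.

## Problem sizes and numerical choices

The cohort-scale regression (also run by `scripts/acceptance.R`) simulates
30 participants (~162,600 samples), splits 25/5 by participant, trains the
GRU on training windows thinned to stride 4 (~34,000 windows — neighbouring
stride-1 windows are 95 % redundant) for the default 15 epochs, calibrates
the baseline over a 45-point grid on the full training recordings, and
evaluates both detectors on stride-1 windows of the held-out participants.
Numerical details worth knowing: rolling statistics use cumulative sums
with partial windows at sequence starts; softmax subtracts the row maximum;
log-loss clamps probabilities at \eqn{10^{-12}}; timestamps are kept on an
exact 0.1 s grid (serialized via an integer decisecond clock) and validated
against it; ΔSVMa at a recording's first sample is 0 rather than dropping
the first window.

## Known limitations

* The simulator's magnitudes are plausible, not measured; absolute
  sensitivities/false-alarm counts on synthetic data say nothing
  quantitative about field performance — only the *orderings* (GRU at
  least as sensitive on falls and stumbles; threshold false alarms
  concentrated on rough-surface scenarios) are the reproduction target.
* The baseline is a reconstruction of a benchmark whose exact thresholds,
  multi-sensor fusion and portent categories are unpublished; it uses the
  single waist stream only.
* Single-platform reproducibility only: BLAS summation order can differ
  across builds.
* The GRU trains with plain cross-entropy by default; under much rarer
  target events than the default plan provides, class weighting or event
  oversampling would be needed.
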