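---
title: "Methods: auditing PPG- and rPPG-based blood-pressure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing PPG- and rPPG-based blood-pressure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

End-to-end neural networks that regress systolic and diastolic blood
pressure (SBP/DBP, in mmHg) from the photoplethysmogram (PPG) — or from its
contactless, camera-derived cousin rPPG — are routinely reported with
optimistic mean errors. Two methodological pitfalls dominate. First, when a
dataset is split into train/validation/test at the *sample* level, windows
from the same subject land on both sides of the boundary; a network can then
recognize the subject from pulse morphology and recall that subject's blood
pressure instead of inferring it. Second, a single overall mean absolute
error (MAE) hides a strong dependence of the error on the underlying BP
value: predictors concentrate on the mode of the label distribution and err
badly in the hypo- and hypertensive tails, which is exactly where clinical
use would need them.

`ppgbp` implements the full assessment pipeline needed to expose both
effects — windowing and quality gating of continuous signals, ground-truth
extraction from arterial blood pressure (ABP) waveforms, subject-aware
dataset construction, a small zoo of 1-D network architectures, training
with early stopping, subject personalization, rPPG transfer learning, and
bin-wise evaluation — and couples it to a synthetic-cohort generator so that
every stage, and every qualitative finding, is testable without access to
clinical waveform databases.

## The synthetic cohort generator

Each synthetic subject is a `subject_profile`: baseline SBP/DBP and heart
rate, a slow sinusoidal BP drift (amplitude in mmHg, period in seconds)
with a beat-level AR(1) jitter that scales with the drift amplitude (so
drift-free subjects are exactly stationary), additive PPG noise, and a
record duration drawn from a long-tailed log-normal so cohorts span records
from minutes to hours.

The PPG beat is a smooth two-bump template: an asymmetric Gaussian systolic
peak plus a Gaussian dicrotic bump. Its four shape parameters (systolic
width, dicrotic amplitude, dicrotic delay, asymmetry) are a *linear*
population function of the instantaneous (SBP, DBP, HR) — linearity keeps
the learning problem solvable by small networks at desk scale — plus a
fixed, subject-specific offset vector. That offset is the load-bearing
design element: it confounds the morphology→BP mapping across subjects,
which is what makes train/test leakage *detectable*. A model tested on its
own training subjects can exploit subject identity; one tested on unseen
subjects cannot.

The ABP channel shares the beat grid. Within each complete beat the sampled
pulse shape is rescaled to span exactly `[DBP_k, SBP_k]`, so peak detection
recovers the per-beat ground truth to within interpolation error, and the
median-based labels recover drift-free baselines essentially exactly.

Camera (rPPG) data are emulated as per-frame ROI-mean RGB triplets: a
common-mode multiplicative baseline wander, channel-specific pulse
modulation with relative strengths (R, G, B) = (0.33, 0.77, 0.53) — the
typical skin-reflection ordering; the exact values are free parameters —
optional exponentially decaying motion-artifact transients, and sensor
noise. Reference BP is emitted on an inclusive one-minute grid by reading
the drift trajectory at each minute mark, the way a bedside monitor reports
it. Two pulse renderings are available: the subject's contact-PPG
morphology, and a "camera" rendering of the *same* BP-dependent morphology
(broader systolic peak, attenuated and delayed dicrotic bump, rounded
baseline). The second is deliberately a different waveform family — the
domain shift that transfer learning must bridge — while still encoding
blood pressure; a BP-independent camera pulse would contradict the premise
that rPPG carries the same physiological information as PPG, and would
leave a transferred model nothing to recover.

What the generator does *not* emulate: pathology-specific waveform classes,
medication effects, sensor contact-pressure artifacts, or non-stationary
subject states. Passing tests on this cohort therefore demonstrate that the
pipeline machinery is correct and that the leakage/tail/personalization
effects follow from subject-confounded morphology alone — not that any
architecture would reach a particular accuracy on clinical data.

## Preprocessing

The canonical stage order is fixed and asserted:
`bandpass → window → snr_gate → normalize`.

* **Band-pass**: 4th-order Butterworth, 0.5–8 Hz, applied forward and
  backward (`signal::filtfilt`) so that zero phase distortion preserves the
  morphology that downstream models consume. The ABP channel is never
  filtered.
* **Heart-rate estimation**: the strongest component of a zero-padded FFT
  magnitude spectrum within 0.5–3 Hz (30–180 beats/min), with bin width at
  most 0.02 Hz.
* **Windowing**: `const_time` cuts fixed-duration segments (possibly
  interrupting beats); `const_beats` estimates the heart rate on a 20 s
  neighborhood of each candidate start, spans exactly `N_P` estimated
  beats, and Fourier-resamples the span to `N_P × 125` samples — an
  effective heart rate of 60 beats/min. The admissible length grid is
  1, 2, 5, 7, 9, 11, 13, 15, 17, 20 (seconds or beats); 7 beats is the
  default working point. ABP segments always cover the same source span and
  are *not* resampled — labels are medians, which are resampling-invariant
  anyway. Windows are consecutive and disjoint by default.
* **Derivatives**: optional first/second channels by central differences
  (one-sided ends, scaled by the sampling rate), the second derivative
  being the first-derivative operator applied twice; computed before
  normalization.
* **Quality gating**: the spectral signal-to-noise ratio is
  `10·log10(E_P/E_S)` where `E_P` sums periodogram energy within ±0.2 Hz of
  the pulse peak and of its first harmonic, and `E_S` sums the remaining
  energy in 0.5–8 Hz. Windows below −7 dB are discarded (boundary
  inclusive: −7 dB survives). The band half-width is a config knob; the
  measure degrades below ~4 s windows.
* **Normalization**: per window and channel to zero mean, unit variance
  (population convention, divide by N). Constant windows cannot be
  standardized and are dropped with a flagged reason. Normalization is
  deliberately last; it would not change the SNR, but the order is part of
  the pipeline contract.
* **POS**: the plane-orthogonal-to-skin projection uses 1.6 s sliding
  windows, temporal normalization by per-channel running means, projection
  rows (0, 1, −1) and (−2, 1, 1), recombination
  `h = s1 + (sd(s1)/sd(s2))·s2`, and mean-removed overlap-add. The output
  is exactly invariant to global intensity scaling and exactly zero for
  common-mode input.

## Labels and plausibility

Systolic peaks are local ABP maxima passing a minimum inter-peak distance
of half the expected beat period and a prominence of at least 10% of the
segment's amplitude range; diastolic values are the troughs between
consecutive systolic peaks ("diastolic peaks" read as troughs). The window
label is the median of each, and the heart rate for the plausibility rule
comes from ABP inter-peak intervals — never from the PPG, so label validity
cannot depend on PPG quality. Labels outside 75–165 mmHg (SBP), 40–80 mmHg
(DBP) or 50–140 beats/min are rejected; bounds are inclusive and rules are
checked in that order, a doubly-violating window being counted once under
the first rule. Windows with fewer than two detected peaks are rejected as
`too_few_peaks`.

## Datasets

Subjects contribute at most 2000 windows each (uniform, seeded
subsampling). The **non-mixed** split assigns each subject to exactly one
of train/validation/test; surplus subjects are tagged `excluded`, never
silently dropped. The **mixed** split pools the capped windows of the
selected subjects and cuts the shuffled samples by fractions
(2/3, 1/6, 1/6) — chosen to mirror a 1,000,000 / 250,000 / 250,000 sample
ratio at full scale. Disjointness (of subject sets, respectively sample
sets) is asserted on every construction. All randomness flows from one
split-level seed through deterministic per-subject derived seeds.

For personalization, a subject's windows are ordered by source offset:
the first 20% is the `first_20` calibration set; the last 80% is split at
its midpoint into a spare pool (first half) and the test set (second
half); `random_20` draws its calibration from the union of the first 20%
and the spare pool. The test set is therefore identical under both
strategies, and calibration ∩ test = ∅ is asserted.

## Models

Five architectures sit behind one registry, all ending in a two-neuron
linear regression head (SBP, DBP):

* `alexnet1d` — the AlexNet layout with 1-D convolutions along time
  (kernels 11/5/3/3/3, channel counts 96/256/384/384/256, two dense stages
  with dropout);
* `resnet1d` — ResNet-18's stem and 2-2-2-2 residual stages with channels
  64/128/256/512, 1×1 strided shortcuts where shapes change;
* `spectrotemporal` — three input channels through a residual 1-D conv
  stack in parallel with a log-magnitude spectrogram branch (fixed STFT,
  conv over frames, linear time interpolation to the temporal branch's
  length), concatenated into one GRU layer, then dense; documented as an
  approximation and fully config-overridable;
* `cnn_lstm` — one conv layer (32 filters, kernel 5, stride 1, ReLU), three
  bidirectional LSTM layers of 64, 64, 32 units per direction, a 128-unit
  dense layer, then the head. Three recurrent layers (not four) were
  chosen where the sources disagree; the enumerated sizes are read as
  per-direction.
* `mean_regressor` — predicts the training-set mean SBP/DBP everywhere;
  its test MAE has the closed form `mean |y − ȳ_train|`.

The engine behind them is a compact, pure-R implementation with manual
backpropagation (convolution by patch-matrix multiplication, exact
gradients verified against numerical differentiation to ~1e−9 relative
error). Two deliberate simplifications: batch normalization is omitted
from the ResNet translation — at the depths and batch sizes this engine
targets, He-initialized residual blocks train stably without it — and a
`width` hyperparameter scales channel counts down for single-CPU
experiments while the defaults keep the published sizes.

Training uses Adam (learning rate 0.001), mean squared error over the
(SBP, DBP) pair, batch size 128, up to 200 epochs with patience 10 on the
validation MAE, and restores the best (not last) checkpoint. One
non-obvious choice: for a freshly built model the head bias is warm-started
at the training-label means, so optimization learns residuals around the
cohort mean instead of spending thousands of steps climbing from zero
output to the ~120 mmHg label scale. A window-id audit trail records
everything optimization consumed and training refuses a split whose test
ids intersect it.

## Personalization and rPPG transfer

Personalization continues optimization of *all* layers on the calibration
windows (the freeze is specified only for rPPG transfer), with the
temporally last 10% of the calibration set as the early-stopping monitor,
and evaluates only on the subject's reserved test windows.

rPPG transfer rotates leave-two-out folds over the (deterministically
ordered) subjects: fold *k* tests on subject *k*, validates on subject
*k*+1 (cyclic), and fine-tunes on the rest — so each subject is tested
exactly once. Only the regression head is trainable; since everything
below it is frozen, the head is optimized on features computed once per
window, which is mathematically identical to backpropagating through the
frozen body and far cheaper. The freeze contract is asserted *exactly*:
an MD5 fingerprint of all serialized non-head weights must be bit-identical
before and after. Optional personalization adds the test subject's
first-20% or random-20% windows to the fine-tuning set; the test windows
are the complement of the union of both candidate calibration subsets, so
all scenarios share one test set.

## Evaluation

Overall MAE per target; bin-wise MAE in 10 mmHg bins anchored at the lower
plausibility bound (half-open `[low, high)`, final bin closed, so every
in-range sample falls in exactly one bin); the count-weighted bin mean
reproduces the overall MAE to 1e−9 by construction and is asserted on
every report. Error-distribution comparisons use a two-sample
Kolmogorov–Smirnov test on per-window absolute errors (the only sample
unit that yields usable sizes) or a paired t-test over matched
(architecture, window length, repetition) cells; a zero-variance paired
difference returns a defined degenerate result instead of crashing. No
multiple-testing correction is applied; reports state how many tests were
run implicitly through their comparison lists. The BHS-style grade is the
fraction of absolute errors under 10 mmHg, passing above 85%.

## The desk-scale study conditions

The shipped experiments run on one CPU in minutes, with sizes chosen once:

* leakage experiment: 50 subjects, record durations log-normal around
  180 s (150–600 s), 7-beat windows, a width-0.125 `alexnet1d` with one
  256-unit dense stage, 20-epoch budget with patience 5, subject fractions
  0.6/0.2/0.2 for the non-mixed split;
* BP-drift periods in this cohort are 30–90 s so that any 20% calibration
  span covers at least one full pressure cycle. This mirrors the coverage
  a first-20% calibration has in multi-hour clinical records; with drift
  periods comparable to the whole record, the `first_20` strategy would be
  handicapped by a scale artifact (its windows would sample a single drift
  phase) rather than by anything physiological.
* personalization: the 10 non-mixed test subjects, 20-epoch fine-tuning;
* transfer: 17 camera subjects at 32 frames/s, 360 s each, POS extraction,
  7-beat windows, head-only fine-tuning for up to 60 epochs;
* the determinism check reruns a 6-subject pipeline end to end and demands
  bit-identical reports.

Under these conditions the mixed split beats the non-mixed split on both
targets for every probed seed, the outermost occupied SBP bins err roughly
twice as badly as the modal bin under non-mixed training, personalization
improves 9–10 of 10 held-out subjects under either calibration strategy
with a between-strategy gap smaller than the between-seed spread (and of
inconsistent sign), and head-only rPPG fine-tuning lowers the median
per-subject SBP MAE while the body fingerprint stays bit-identical. These
are directions and orderings, not clinical accuracies: absolute numbers
depend on the synthetic cohort's offset spread and drift amplitudes.

## Numerical choices and degenerate inputs

Fourier resampling truncates/zero-pads the DFT, splitting the Nyquist bin
when upsampling an even-length input (where it matches the common
scientific-computing resamplers to machine precision) and folding the
conjugate pair into the output Nyquist bin when downsampling — a
convention choice at a bin whose information is being discarded anyway. All-zero
segments make the heart rate undefined and raise an error; a zero rest-band
energy reports +Inf SNR with a flag rather than crashing; constant windows
are dropped at normalization with a reason; records shorter than one window
produce an empty window set, not an error. Every library function that
draws random numbers takes or derives an explicit seed and restores the
caller's RNG state; per-subject and per-fold seeds are derived
deterministically from the experiment seed and a string key, and stay below
2^31.

## Known limitations

The generator's linear morphology→BP mapping and additive subject offsets
are far simpler than real inter-subject variability; they make leakage
detectable but cannot calibrate how large it is in clinical data. The
engine is CPU-bound pure R: it is sized for cohorts of tens of subjects
and thousands of windows, not for million-sample trainings. The
spectro-temporal architecture approximates its published counterpart's
structure (branch layout, GRU fusion) rather than reproducing it layer for
layer. The waveform-format adapter reads only format-16 PLETH/ABP records
and is a convenience, not a tested ingestion path for arbitrary PhysioNet
holdings.
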