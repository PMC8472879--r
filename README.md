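# ppgbp

An assessment pipeline for cuffless blood-pressure prediction from
photoplethysmography (PPG) and camera-derived remote PPG (rPPG) signals.

Neural networks that regress systolic/diastolic blood pressure (SBP/DBP)
from pulse waveforms are often evaluated in ways that flatter them: when a
dataset is split at the *sample* level, windows from the same subject end
up in both training and test sets, and a network can recognize the subject
from pulse morphology and recall that subject's blood pressure instead of
inferring it; and a single overall mean absolute error (MAE) hides the
sharp increase of the error toward rare hypo- and hypertensive values.
`ppgbp` is for researchers who want to *audit* such pipelines: it provides
every stage — signal windowing, spectral quality gating, ABP-derived
ground truth, subject-aware dataset construction, a small 1-D architecture
zoo, personalization and transfer protocols, bin-wise evaluation — plus a
seeded synthetic-cohort generator whose subject-specific morphology
offsets make train/test leakage detectable by construction.

## The core quantities

* Windows are cropped either as fixed-duration segments (`const_time`) or
  as exactly `N_P` pulse cycles resampled to `N_P × 125` samples — an
  effective heart rate of 60 beats/min (`const_beats`, default
  `N_P = 7`).
* Window quality is the spectral signal-to-noise ratio
  `SNR = 10·log10(E_P / E_S)` [dB], where `E_P` is the periodogram energy
  within ±0.2 Hz of the pulse peak and its first harmonic and `E_S` the
  remaining energy in 0.5–8 Hz; windows below −7 dB are discarded.
* Labels are per-window medians of the ABP systolic peaks and diastolic
  troughs, kept only inside 75–165 mmHg (SBP), 40–80 mmHg (DBP),
  50–140 beats/min.
* Models are trained with Adam (α = 0.001) on a mean squared error over
  the (SBP, DBP) pair, with early stopping (patience 10) restoring the
  best validation checkpoint; evaluation reports overall and 10 mmHg
  bin-wise MAE against a mean-regressor baseline, with Kolmogorov–Smirnov
  and paired-t comparisons, and the fraction of absolute errors under
  10 mmHg (85% pass threshold).

There is no deep-learning framework underneath: the package ships a
compact pure-R engine (1-D convolutions, residual blocks, bidirectional
LSTM, GRU, Adam) with hand-written backpropagation, verified against
numerical gradients.

## A worked example

```r
library(ppgbp)

profile <- subject_profile("S0001", base_hr = 72, base_sbp = 128,
                           base_dbp = 71, bp_drift_amplitude = 6,
                           record_duration = 300, seed = 1)
record <- generate_subject_record(profile)
record
#> <bp_wave_record> subject S0001: 37500 samples @ 125 Hz (300.0 s), paired ABP

windows <- preprocess_record(record, windowing_config("const_beats", 7),
                             snr_threshold = -7)
windows
#> <bp_window_set> 51 windows x 875 samples x 1 channel(s), strategy const_beats

head(label_windows(windows), 3)
#>        sbp      dbp median_hr n_systolic_peaks valid reject_reason
#> 1 133.6791 73.97090  72.46546                7  TRUE          none
#> 2 133.0721 73.49652  72.11538                7  TRUE          none
#> 3 132.4184 73.28168  71.09164                7  TRUE          none
```

Each row is one 7-beat window: the median systolic/diastolic pressure over
its beats (here ≈133/74 mmHg — the subject's 128/71 baseline plus the
slow drift), the ABP-derived heart rate, and the plausibility verdict.

A small end-to-end run — synthesize a cohort, preprocess, label, split by
subject, train, evaluate:

```r
cfg <- default_run_config()
cfg$cohort$n_subjects <- 8
cfg$cohort$seed <- 11
cfg$cohort$subject_size_distribution <- list(meanlog = log(150), sdlog = 0.3,
                                             min_s = 120, max_s = 300)
cfg$model$hyperparams <- list(width = 0.1, dense = c(128))
cfg$training$max_epochs <- 10
cfg$training$patience <- 3
cfg$training$batch_size <- 64
cfg$seed <- 11
res <- run_pipeline(cfg)
res$report
#> <bp_evaluation_report> n = 18
#>   MAE: SBP 3.93 mmHg, DBP 1.15 mmHg
#>   mean-regressor baseline: SBP 3.97, DBP 1.29 mmHg
#>   within 10 mmHg: SBP 100.0%, DBP 100.0% (BHS pass: TRUE / TRUE)
```

At this toy size (one unseen test subject) the network barely beats the
mean regressor — which is itself the point the package exists to make
visible. The real experiments are one call each:

```r
exp <- run_leakage_experiment(n_subjects = 50, seed = 1)   # mixed vs non-mixed
pers <- run_personalization_experiment(exp)                # per-subject fine-tuning
pools <- build_rppg_pools(n_subjects = 17, seed = 99)      # POS-extracted camera pulses
tr <- transfer_to_rppg(exp$non_mixed$model, pools)         # head-only transfer
```

A thin command-line front end covering cohort synthesis, preprocessing and
the pipeline lives at `inst/cli/ppgbp.R`.

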