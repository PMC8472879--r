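#' End-to-end synthetic experiments
#'
#' These functions chain the generator, preprocessing, labelling, splitting,
#' training and evaluation stages into the package's standard experiments:
#' the mixed-versus-non-mixed leakage comparison, subject personalization,
#' and the rPPG transfer protocol. Every experiment is fully determined by
#' its seed.
#'
#' @name ppgbp-experiments
NULL

#' Windows, labels and pool from a cohort
#'
#' Runs the canonical preprocessing order (band-pass, crop, SNR gate,
#' normalize), labels windows from the un-resampled ABP spans, applies the
#' plausibility filters, and pools the survivors across subjects.
#'
#' @param cohort A [generate_cohort()] result.
#' @param wcfg A [windowing_config()].
#' @param snr_threshold SNR gate in dB.
#' @param plaus A [plausibility_config()].
#' @param derivatives Add derivative channels.
#' @return A list with the `pool` (class `bp_window_pool`) and per-stage
#'   attrition `counts`.
#' @export
cohort_to_pool <- function(cohort, wcfg = windowing_config("const_beats", 7),
                           snr_threshold = -7,
                           plaus = plausibility_config(),
                           derivatives = FALSE) {
  counts <- c(cropped = 0L, snr_gated = 0L, normalized = 0L, labelled = 0L)
  pairs <- lapply(cohort$records, function(r) {
    ws <- preprocess_record(r, wcfg, snr_threshold,
                            derivatives = derivatives)
    at <- attr(ws, "attrition")
    counts[names(at)] <<- counts[names(at)] + at
    if (!n_windows(ws)) return(NULL)
    labs <- label_windows(ws, plaus)
    fl <- filter_labelled_windows(ws, labs)
    counts["labelled"] <<- counts["labelled"] + n_windows(fl$windows)
    if (!n_windows(fl$windows)) NULL else fl
  })
  pairs <- Filter(Negate(is.null), pairs)
  list(pool = build_pool(pairs), counts = counts)
}

# Desk-scale study conditions: records of a few minutes (the clinical
# records are hours long), with BP-drift periods short enough that any 20%
# calibration span covers at least one full pressure cycle - the same
# coverage regime a first-20% calibration enjoys in multi-hour records.
leakage_cohort_config <- function(n_subjects, seed) {
  cohort_config(
    n_subjects = n_subjects, seed = seed,
    subject_size_distribution = list(meanlog = log(180), sdlog = 0.5,
                                     min_s = 150, max_s = 600),
    population = list(drift_period_range = c(30, 90)))
}

#' Mixed vs non-mixed leakage experiment
#'
#' Generates a synthetic cohort with subject-specific morphology offsets,
#' builds capped pools, trains the same architecture under a subject-aware
#' (non-mixed) and a sample-level (mixed) split, and evaluates both on
#' their test partitions against the mean-regressor baseline. Because the
#' morphology-to-BP mapping is confounded by the per-subject offset, a model
#' tested on its own training subjects (mixed) can exploit subject identity
#' and achieves a lower error than one tested on unseen subjects
#' (non-mixed).
#'
#' @param n_subjects Cohort size (default 50).
#' @param seed Experiment seed.
#' @param architecture Architecture name (default `"alexnet1d"`).
#' @param hyperparams Hyperparameters (default: width 0.125, one 256-unit
#'   dense stage - a small CNN sized for single-CPU runs).
#' @param wcfg Windowing configuration (default 7-beat windows).
#' @param cap Per-subject sample cap.
#' @param train_cfg A [training_config()]; the default shortens the epoch
#'   budget to 30 with patience 5 for desk-scale runs.
#' @param subject_fractions Non-mixed train/val/test subject fractions.
#' @return List with evaluation reports and splits for both modes, the
#'   trained models, the pool and the cohort.
#' @export
run_leakage_experiment <- function(n_subjects = 50, seed = 1,
                                   architecture = "alexnet1d",
                                   hyperparams = list(width = 0.125,
                                                      dense = c(2048)),
                                   wcfg = windowing_config("const_beats", 7),
                                   cap = 2000,
                                   train_cfg = training_config(
                                     max_epochs = 20, patience = 5,
                                     batch_size = 128),
                                   subject_fractions = c(0.6, 0.2, 0.2)) {
  cohort <- generate_cohort(leakage_cohort_config(n_subjects, seed))
  cp <- cohort_to_pool(cohort, wcfg)
  pool <- cap_subjects(cp$pool, cap, seed)
  ns <- length(unique(pool$subject))
  n_tr <- max(1L, round(subject_fractions[1] * ns))
  n_va <- max(1L, round(subject_fractions[2] * ns))
  n_te <- max(1L, ns - n_tr - n_va)

  split_nm <- split_non_mixed(pool, n_tr, n_va, n_te, seed = seed,
                              cap = cap)
  split_mx <- split_mixed(pool, seed = seed, cap = cap)

  input_len <- dim(ensure_3d(pool$x))[2]
  fit_one <- function(split, tag) {
    ms <- model_spec(architecture, input_length = input_len,
                     input_channels = dim(ensure_3d(pool$x))[3],
                     hyperparams = hyperparams,
                     seed = derive_seed(seed, tag))
    cfg <- train_cfg
    cfg$seed <- derive_seed(seed, paste0(tag, "-train"))
    fit <- train_model(build_model(ms), split, cfg)
    baseline <- mean_regressor_fit(split$train$y)
    pred <- predict_bp(fit$model, split$test$x)
    list(model = fit$model, history = fit$history,
         report = evaluation_report(pred, split$test$y, baseline),
         predictions = pred)
  }
  nm <- fit_one(split_nm, "non_mixed")
  mx <- fit_one(split_mx, "mixed")
  list(non_mixed = nm, mixed = mx, split_non_mixed = split_nm,
       split_mixed = split_mx, pool = pool, cohort = cohort,
       attrition = cp$counts, seed = seed)
}

#' Personalization experiment on non-mixed test subjects
#'
#' Fine-tunes the non-mixed pre-trained model on each selected test
#' subject's 20% calibration windows (both selection strategies) and
#' compares the subject's test MAE before and after personalization. The
#' test windows are identical across strategies by construction.
#'
#' @param exp A [run_leakage_experiment()] result.
#' @param n_subjects Number of test subjects to personalize (default 10).
#' @param train_cfg A [training_config()] for fine-tuning (short budget).
#' @param min_windows Minimum windows a subject needs to qualify.
#' @return Data frame: one row per (subject, strategy) with pre/post MAE.
#' @export
run_personalization_experiment <- function(exp, n_subjects = 10,
                                           train_cfg = training_config(
                                             max_epochs = 20, patience = 5,
                                             batch_size = 32),
                                           min_windows = 10,
                                           seed = exp$seed) {
  split <- exp$split_non_mixed
  pool <- exp$pool
  test_subjects <- names(which(split$subject_assignment == "test"))
  sizes <- vapply(test_subjects,
                  function(s) sum(pool$subject == s), 0L)
  eligible <- test_subjects[sizes >= min_windows]
  chosen <- utils::head(sort(eligible), n_subjects)
  out <- list()
  for (s in chosen) {
    sp <- subset_pool(pool, which(pool$subject == s))
    for (strategy in c("first_20", "random_20")) {
      part <- make_personalization_partition(sp, strategy, seed = exp$seed)
      pred_pre <- predict_bp(exp$non_mixed$model, part$test$x)
      mae_pre <- mae(pred_pre, part$test$y)
      cfg <- train_cfg
      cfg$seed <- derive_seed(seed, paste(s, strategy))
      pers <- personalize(exp$non_mixed$model, part, cfg)
      pred_post <- predict_bp(pers$model, part$test$x)
      mae_post <- mae(pred_post, part$test$y)
      out[[length(out) + 1L]] <- data.frame(
        subject = s, strategy = strategy,
        n_calibration = pool_size(part$calibration),
        n_test = pool_size(part$test),
        mae_sbp_pre = unname(mae_pre[1]), mae_dbp_pre = unname(mae_pre[2]),
        mae_sbp_post = unname(mae_post[1]),
        mae_dbp_post = unname(mae_post[2]))
    }
  }
  do.call(rbind, out)
}

#' Build per-subject rPPG window pools from synthetic traces
#'
#' For each subject: generate an RGB trace with an embedded camera-style
#' pulse (a deliberately different waveform from the contact-PPG template,
#' i.e. a domain shift), extract the pulse with POS, crop 7-beat windows,
#' gate by SNR, normalize, and label from the minute-grid reference BP.
#'
#' @param n_subjects Number of subjects (default 17).
#' @param seed Seed.
#' @param duration_s Trace duration per subject in seconds.
#' @param fs Camera frame rate in Hz.
#' @param pulse_strength Embedded pulse modulation depth.
#' @param wcfg Windowing configuration.
#' @param snr_threshold SNR gate in dB.
#' @return Named list of single-subject `bp_window_pool`s.
#' @export
build_rppg_pools <- function(n_subjects = 17, seed = 99,
                             duration_s = 360, fs = 32,
                             pulse_strength = 0.4,
                             wcfg = windowing_config("const_beats", 7),
                             snr_threshold = -7) {
  cc <- cohort_config(
    n_subjects = n_subjects, seed = seed,
    subject_size_distribution = list(meanlog = log(duration_s), sdlog = 0,
                                     min_s = duration_s, max_s = duration_s))
  profiles <- with_seed(cc$seed, {
    cohort <- generate_cohort(cc, fs = 50)  # profiles only; records unused
    cohort$profiles
  })
  pools <- list()
  for (p in profiles) {
    tr <- generate_rppg_trace(p, fs = fs, pulse_strength = pulse_strength,
                              artifact_rate = 0,
                              pulse_template = "rppg")
    pulse <- pos_extract(tr$rgb, fs)
    rec <- wave_record(p$subject_id, pulse, abp = NULL, fs = fs)
    ws <- crop_windows(rec, wcfg)
    if (!n_windows(ws)) next
    ws <- compute_window_snr(ws)
    ws <- gate_by_snr(ws, snr_threshold)
    ws <- normalize_windows(ws)
    if (!n_windows(ws)) next
    labs <- label_windows_from_reference(ws, tr$reference)
    keep <- which(labs$valid)
    if (!length(keep)) next
    pools[[p$subject_id]] <- build_pool(list(list(
      windows = subset_window_set(ws, keep),
      labels = labs[keep, , drop = FALSE])))
  }
  pools
}

#' Deterministic small-scale pipeline run
#'
#' Executes the full synthetic pipeline (cohort, preprocessing, labelling,
#' split, training, evaluation) for one configuration and returns the
#' evaluation report. Identical configuration and seed reproduce every
#' report value exactly.
#'
#' @param cfg Configuration list as from [default_run_config()]; validated
#'   before anything runs.
#' @return List with the `report`, the trained `model`, the `split` and the
#'   attrition counts.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  validate_run_config(cfg)
  cc_args <- list(
    n_subjects = cfg$cohort$n_subjects, seed = cfg$cohort$seed,
    fraction_reject_material = cfg$cohort$fraction_reject_material %||% 0)
  if (!is.null(cfg$cohort$subject_size_distribution)) {
    cc_args$subject_size_distribution <- cfg$cohort$subject_size_distribution
  }
  cohort <- generate_cohort(do.call(cohort_config, cc_args))
  wcfg <- suppressWarnings(windowing_config(
    cfg$windowing$strategy, cfg$windowing$length_parameter,
    overlap = cfg$windowing$overlap %||% 0))
  plaus <- plausibility_config(cfg$plausibility$sbp_range,
                               cfg$plausibility$dbp_range,
                               cfg$plausibility$hr_range)
  cp <- cohort_to_pool(cohort, wcfg, cfg$snr_threshold, plaus)
  pool <- cap_subjects(cp$pool, cfg$split$cap, cfg$seed)
  ns <- length(unique(pool$subject))
  if (cfg$split$mode == "non_mixed") {
    fr <- cfg$split$subject_fractions %||% c(0.6, 0.2, 0.2)
    n_tr <- max(1L, round(fr[1] * ns))
    n_va <- max(1L, round(fr[2] * ns))
    n_te <- max(1L, ns - n_tr - n_va)
    split <- split_non_mixed(pool, n_tr, n_va, n_te, seed = cfg$seed,
                             cap = cfg$split$cap)
  } else {
    split <- split_mixed(pool, seed = cfg$seed, cap = cfg$split$cap)
  }
  input_len <- dim(ensure_3d(pool$x))[2]
  ms <- model_spec(cfg$model$architecture, input_length = input_len,
                   input_channels = dim(ensure_3d(pool$x))[3],
                   hyperparams = cfg$model$hyperparams,
                   seed = derive_seed(cfg$seed, "model"))
  tcfg <- training_config(
    learning_rate = cfg$training$learning_rate,
    max_epochs = cfg$training$max_epochs,
    patience = cfg$training$patience,
    batch_size = cfg$training$batch_size,
    monitor = cfg$training$monitor %||% "val_mae",
    seed = derive_seed(cfg$seed, "train"))
  fit <- train_model(build_model(ms), split, tcfg)
  baseline <- mean_regressor_fit(split$train$y)
  pred <- predict_bp(fit$model, split$test$x)
  report <- evaluation_report(pred, split$test$y, baseline,
                              bin_width = cfg$evaluation$bin_width)
  list(report = report, model = fit$model, split = split,
       attrition = cp$counts)
}
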