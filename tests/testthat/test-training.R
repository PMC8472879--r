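toy_split <- function(n_tr = 60, n_va = 20, n_te = 20, T = 125, seed = 1) {
  set.seed(seed)
  mk <- function(n, tag) {
    structure(list(
      x = matrix(rnorm(n * T), n),
      y = cbind(sbp = runif(n, 100, 140), dbp = runif(n, 55, 75)),
      subject = rep(tag, n), offset = seq_len(n),
      id = paste0(tag, "@", seq_len(n))),
      class = "bp_window_pool")
  }
  structure(list(mode = "non_mixed", train = mk(n_tr, "tr"),
                 val = mk(n_va, "va"), test = mk(n_te, "te"),
                 subject_assignment = c(tr = "train", va = "val",
                                        te = "test"),
                 per_subject_cap = 2000, seed = seed),
            class = "bp_dataset_split")
}

test_that("early stopping waits out the patience and restores the best epoch", {
  vals <- c(10, 9, 9, 9, 9, 9, 9, 9, 9, 9, 9, 9)
  st <- early_stopping_state(patience = 10)
  stopped_at <- NA
  for (e in seq_along(vals)) {
    st <- early_stopping_update(st, vals[e], e)
    if (st$stop) { stopped_at <- e; break }
  }
  expect_equal(stopped_at, 12)
  expect_equal(st$best_epoch, 2)
  # ever-improving metric never stops
  st2 <- early_stopping_state(10)
  for (e in 1:200) st2 <- early_stopping_update(st2, 100 - e, e)
  expect_false(st2$stop)
  expect_equal(st2$best_epoch, 200)
})

test_that("training is seed-deterministic and restores the best checkpoint", {
  sp <- toy_split()
  ms <- model_spec("alexnet1d", 125, 1,
                   list(width = 0.05, dense = c(32), dropout = 0.2),
                   seed = 4)
  cfg <- training_config(max_epochs = 6, patience = 3, batch_size = 32,
                         seed = 7)
  f1 <- train_model(build_model(ms), sp, cfg)
  f2 <- train_model(build_model(ms), sp, cfg)
  expect_identical(fingerprint_weights(f1$model),
                   fingerprint_weights(f2$model))
  expect_identical(f1$history, f2$history)
  expect_equal(f1$best_epoch, which.min(f1$history$val_mae))
  # the audit trail records what optimization consumed
  expect_setequal(f1$model$train_window_ids,
                  c(sp$train$id, sp$val$id))
})

test_that("training refuses a split whose test windows leak into optimization", {
  sp <- toy_split()
  sp$val <- sp$test   # corrupt the split
  ms <- model_spec("alexnet1d", 125, 1, list(width = 0.05, dense = c(16)),
                   seed = 1)
  expect_error(train_model(build_model(ms), sp,
                           training_config(max_epochs = 2, patience = 1)),
               "audit trail")
})

test_that("configuration invariants are enforced", {
  expect_error(training_config(patience = 10, max_epochs = 10), "below")
  expect_error(training_config(learning_rate = 0), "positive")
  expect_error(transfer_config("everything"), "arg")
})

test_that("personalization trains on calibration only and needs a trained model", {
  sp <- toy_split()
  ms <- model_spec("alexnet1d", 125, 1,
                   list(width = 0.05, dense = c(32), dropout = 0), seed = 4)
  cfg <- training_config(max_epochs = 4, patience = 2, batch_size = 32,
                         seed = 7)
  fit <- train_model(build_model(ms), sp, cfg)

  subj <- sp$test
  part <- make_personalization_partition(subj, "first_20", seed = 1)
  expect_error(personalize(build_model(ms), part, cfg), "pre-trained")

  pers <- personalize(fit$model, part, cfg)
  expect_true(all(part$calibration$id %in% pers$model$train_window_ids))
  expect_false(any(part$test$id %in% pers$model$train_window_ids))

  # a corrupted partition with overlap is a hard error
  bad <- part
  bad$test <- part$calibration
  expect_error(personalize(fit$model, bad, cfg), "overlap")
})

test_that("rPPG transfer freezes everything except the head, exactly", {
  sp <- toy_split()
  ms <- model_spec("alexnet1d", 125, 1,
                   list(width = 0.05, dense = c(32), dropout = 0), seed = 4)
  cfg <- training_config(max_epochs = 5, patience = 2, batch_size = 32,
                         seed = 7)
  fit <- train_model(build_model(ms), sp, cfg)

  set.seed(11)
  pools <- lapply(1:5, function(i) {
    n <- 24
    structure(list(
      x = matrix(rnorm(n * 125), n),
      y = cbind(sbp = runif(n, 100, 140), dbp = runif(n, 55, 75)),
      subject = rep(paste0("R", i), n), offset = seq_len(n),
      id = paste0("R", i, "@", seq_len(n))),
      class = "bp_window_pool")
  })
  names(pools) <- paste0("R", 1:5)
  fp_before <- fingerprint_weights(fit$model)
  res <- transfer_to_rppg(fit$model, pools,
                          transfer_config("final_layer_only", "none"),
                          training_config(max_epochs = 5, patience = 2,
                                          batch_size = 16, seed = 3))
  expect_identical(unname(res$fingerprints["pre"]),
                   unname(res$fingerprints["post"]))
  expect_identical(unname(res$fingerprints["pre"]), fp_before)
  # leave-two-out rotation: every subject tested exactly once
  expect_setequal(res$results$subject, names(pools))
  expect_equal(nrow(res$results), 5)
  expect_false(any(res$results$subject == res$results$val_subject))
  expect_error(transfer_to_rppg(fit$model, pools, transfer_config("all")),
               "final_layer_only")
  expect_error(transfer_to_rppg(fit$model, pools[1:2]), "at least 3")
})

test_that("the window study produces one row per cell for paired comparison", {
  set.seed(2)
  records <- lapply(1:4, function(i) {
    generate_subject_record(subject_profile(
      paste0("WS", i), base_hr = runif(1, 60, 90),
      base_sbp = runif(1, 100, 150), base_dbp = runif(1, 55, 75),
      record_duration = 60, seed = i))
  })
  tab <- run_window_study(
    records, architectures = "alexnet1d", lengths = 2,
    strategies = c("const_time", "const_beats"), repetitions = 2,
    hyperparams = list(width = 0.05, dense = c(16), dropout = 0),
    cfg = training_config(max_epochs = 2, patience = 1, batch_size = 32))
  expect_equal(nrow(tab), 4)  # 2 strategies x 1 length x 1 arch x 2 reps
  expect_setequal(unique(tab$strategy), c("const_time", "const_beats"))
  wide <- reshape(tab, idvar = c("architecture", "length", "repetition"),
                  timevar = "strategy", direction = "wide")
  cmp <- compare_error_distributions(wide$mae_sbp.const_time,
                                     wide$mae_sbp.const_beats, "paired_t")
  expect_true(is.finite(cmp$p_value) || !is.null(cmp$note))
})
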