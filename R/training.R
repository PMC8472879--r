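#' Training, personalization and transfer protocols
#'
#' Networks are optimized with Adam on a mean squared error over the
#' (SBP, DBP) output pair; training stops after `max_epochs` or when the
#' monitored validation metric has not improved for `patience` epochs, and
#' the best checkpoint (not the last) is restored. A window-id audit trail
#' guarantees that no test window ever enters an optimization step.
#'
#' @name ppgbp-training
NULL

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param max_epochs Epoch budget (default 200; the window-length study uses
#'   50).
#' @param patience Early-stopping patience in epochs (default 10; must be
#'   below `max_epochs`).
#' @param batch_size Minibatch size (default 128).
#' @param monitor `"val_mae"` (default: the checkpoint with the lowest
#'   validation MAE is kept) or `"val_loss"`.
#' @param seed Seed controlling shuffling, dropout and initialization order.
#' @param warm_start_head Initialize the head bias at the training-label
#'   means before the first step of a fresh model, so the network learns
#'   residuals around the cohort mean rather than climbing from zero output.
#' @param verbose Print per-epoch progress.
#' @return A list of class `bp_training_config`.
#' @export
training_config <- function(learning_rate = 0.001, max_epochs = 200,
                            patience = 10, batch_size = 128,
                            monitor = c("val_mae", "val_loss"), seed = 1L,
                            warm_start_head = TRUE, verbose = FALSE) {
  monitor <- match.arg(monitor)
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (patience >= max_epochs) stop("`patience` must be below `max_epochs`")
  structure(list(learning_rate = learning_rate, max_epochs = max_epochs,
                 patience = patience, batch_size = batch_size,
                 monitor = monitor, seed = as.integer(seed),
                 warm_start_head = warm_start_head, verbose = verbose),
            class = "bp_training_config")
}

#' Transfer-learning configuration
#'
#' @param trainable_scope `"final_layer_only"` (required for rPPG transfer)
#'   or `"all"`.
#' @param personalization `"none"`, `"first_20"` or `"random_20"`.
#' @return A list of class `bp_transfer_config`.
#' @export
transfer_config <- function(trainable_scope = c("final_layer_only", "all"),
                            personalization = c("none", "first_20",
                                                "random_20")) {
  structure(list(trainable_scope = match.arg(trainable_scope),
                 personalization = match.arg(personalization)),
            class = "bp_transfer_config")
}

# --- early stopping ---------------------------------------------------------

#' Early-stopping tracker
#'
#' Strict-improvement rule: the wait counter resets whenever the monitored
#' value improves on the best seen so far and stopping triggers once
#' `patience` consecutive epochs have passed without improvement. The best
#' epoch, not the last, is what training restores.
#'
#' @param patience Number of non-improving epochs tolerated.
#' @return A tracker list; update it with [early_stopping_update()].
#' @export
early_stopping_state <- function(patience) {
  list(patience = patience, best = Inf, best_epoch = 0L, wait = 0L,
       stop = FALSE)
}

#' @rdname early_stopping_state
#' @param state The tracker.
#' @param value Monitored metric for the epoch just finished.
#' @param epoch Epoch number (1-based).
#' @export
early_stopping_update <- function(state, value, epoch) {
  if (value < state$best) {
    state$best <- value
    state$best_epoch <- epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

# --- core fit loop ----------------------------------------------------------

pool_xy <- function(pool) {
  list(x = ensure_3d(pool$x), y = unname(pool$y), id = pool$id)
}

eval_metrics <- function(model, x, y, batch_size) {
  pred <- predict_bp(model, x, batch_size)
  list(loss = mean((pred - y)^2), mae = mean(abs(pred - y)))
}

# Shared optimization loop. `trainable` is "all" or "head". Assumes the RNG
# is already seeded by the caller.
fit_network <- function(model, train, val, cfg, trainable = "all") {
  tr <- pool_xy(train); va <- pool_xy(val)
  n <- dim(tr$x)[1]
  if (!n || !dim(va$x)[1]) stop("train and validation sets must be nonempty")
  nl <- length(model$layers)
  if (cfg$warm_start_head && !model$trained &&
      isTRUE(model$layers[[nl]]$is_head)) {
    model$layers[[nl]]$params$b <- colMeans(tr$y)
  }
  opt <- adam_new(lr = cfg$learning_rate)
  es <- early_stopping_state(cfg$patience)
  best_layers <- model$layers
  history <- data.frame()
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(n)
    ep_loss <- 0; nb <- 0L
    for (at in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[at:min(n, at + cfg$batch_size - 1L)]
      xb <- tr$x[idx, , , drop = FALSE]
      yb <- tr$y[idx, , drop = FALSE]
      fw <- nn_forward(model$layers, xb, train = TRUE)
      err <- fw$out - yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop(sprintf("training diverged (non-finite loss at epoch %d)",
                     epoch))
      }
      gout <- 2 * err / length(err)
      grads <- nn_backward(model$layers, fw$caches, gout)
      st <- adam_step(opt, model$layers, grads,
                      trainable_only_head = trainable == "head")
      opt <- st$opt
      model$layers <- st$layers
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    vm <- eval_metrics(model, va$x, va$y, cfg$batch_size)
    monitored <- if (cfg$monitor == "val_mae") vm$mae else vm$loss
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / nb, val_loss = vm$loss,
      val_mae = vm$mae))
    es <- early_stopping_update(es, monitored, epoch)
    if (es$best_epoch == epoch) best_layers <- model$layers
    if (cfg$verbose) {
      message(sprintf("epoch %3d  train %.3f  val_mae %.3f", epoch,
                      ep_loss / nb, vm$mae))
    }
    if (es$stop) break
  }
  model$layers <- best_layers
  model$trained <- TRUE
  list(model = model, history = history, best_epoch = es$best_epoch)
}

#' Train a model on a dataset split
#'
#' Optimizes on the training partition, monitors the validation partition,
#' and never touches the test partition; window ids consumed by optimization
#' are recorded on the model and asserted disjoint from the split's test
#' ids.
#'
#' @param model A freshly built or pre-trained `bp_model`.
#' @param split A `bp_dataset_split`.
#' @param cfg A [training_config()].
#' @return List with the trained `model` (best validation checkpoint
#'   restored), the per-epoch `history`, and `best_epoch`.
#' @export
train_model <- function(model, split, cfg = training_config()) {
  stopifnot(inherits(model, "bp_model"),
            inherits(split, "bp_dataset_split"),
            inherits(cfg, "bp_training_config"))
  opt_ids <- c(split$train$id, split$val$id)
  if (length(intersect(opt_ids, split$test$id))) {
    stop("audit trail violation: test windows present in optimization data")
  }
  res <- with_seed(cfg$seed,
                   fit_network(model, split$train, split$val, cfg, "all"))
  res$model$train_window_ids <-
    unique(c(res$model$train_window_ids, opt_ids))
  res
}

#' Personalize a trained model on one subject's calibration windows
#'
#' Continues optimization (all layers trainable) on the calibration portion
#' of the subject's data; the temporally last 10% of the calibration windows
#' serve as the early-stopping validation split. Evaluation is only ever
#' meaningful on `partition$test`, which is asserted disjoint from the
#' calibration set.
#'
#' @param model A trained `bp_model`.
#' @param partition A [make_personalization_partition()].
#' @param cfg A [training_config()] (typically with a reduced epoch budget).
#' @return List with the personalized `model` and fit `history`.
#' @export
personalize <- function(model, partition, cfg = training_config()) {
  stopifnot(inherits(model, "bp_model"),
            inherits(partition, "bp_personalization_partition"))
  if (!model$trained) stop("`model` must be pre-trained before personalizing")
  calib <- partition$calibration
  if (length(intersect(calib$id, partition$test$id))) {
    stop("calibration and test windows overlap")
  }
  n <- pool_size(calib)
  if (n == 0) return(list(model = model, history = data.frame()))
  ord <- order(calib$offset)
  n_val <- max(1L, ceiling(0.1 * n))
  val_idx <- ord[(n - n_val + 1L):n]
  tr_idx <- setdiff(ord, val_idx)
  res <- with_seed(derive_seed(cfg$seed, partition$subject_id),
                   fit_network(model, subset_pool(calib, tr_idx),
                               subset_pool(calib, val_idx), cfg, "all"))
  res$model$train_window_ids <-
    unique(c(res$model$train_window_ids, calib$id))
  res
}

# --- rPPG transfer ----------------------------------------------------------

# Head-only optimization on frozen features: mathematically identical to
# backpropagating through the frozen body, but the body forward pass runs
# once per window instead of once per epoch.
fit_head_on_features <- function(head, feat_tr, y_tr, feat_va, y_va, cfg) {
  opt <- adam_new(lr = cfg$learning_rate)
  es <- early_stopping_state(cfg$patience)
  best <- head
  n <- nrow(feat_tr)
  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(n)
    for (at in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[at:min(n, at + cfg$batch_size - 1L)]
      xb <- feat_tr[idx, , drop = FALSE]
      yb <- y_tr[idx, , drop = FALSE]
      fw <- layer_forward(head, xb)
      err <- fw$out - yb
      gout <- 2 * err / length(err)
      bw <- layer_backward(head, fw$cache, gout)
      st <- adam_step(opt, list(head), list(bw$grads))
      opt <- st$opt
      head <- st$layers[[1]]
    }
    val_pred <- layer_forward(head, feat_va)$out
    val_mae <- mean(abs(val_pred - y_va))
    es <- early_stopping_update(es, val_mae, epoch)
    if (es$best_epoch == epoch) best <- head
    if (es$stop) break
  }
  best
}

#' Transfer a PPG-trained model to rPPG windows (final layer only)
#'
#' Leave-two-out rotation over subjects: subjects are ordered
#' deterministically; fold k tests on subject k and validates on subject
#' k+1 (cyclically), fine-tuning the regression head on the remaining
#' subjects while every other weight stays frozen. The freeze is asserted
#' exactly via the non-head weight fingerprint. Optional personalization
#' adds the test subject's first-20% or random-20% calibration windows to
#' the fine-tuning set; the test windows are the complement of the union of
#' both candidate calibration subsets, hence identical across scenarios.
#'
#' @param model A PPG-pre-trained `bp_model`.
#' @param rppg_pools Named list of single-subject `bp_window_pool`s
#'   (at least 3 subjects).
#' @param cfg A [transfer_config()]; the scope must be
#'   `"final_layer_only"`.
#' @param train_cfg A [training_config()] for the head fine-tuning.
#' @return List with `results` (one row per fold: pre/post-fine-tuning MAE
#'   for SBP and DBP) and `fingerprints` (pre/post, identical by contract).
#' @export
transfer_to_rppg <- function(model, rppg_pools, cfg = transfer_config(),
                             train_cfg = training_config()) {
  stopifnot(inherits(model, "bp_model"), inherits(cfg, "bp_transfer_config"))
  if (cfg$trainable_scope != "final_layer_only") {
    stop("rPPG transfer requires trainable_scope = 'final_layer_only'")
  }
  if (length(rppg_pools) < 3) stop("need at least 3 rPPG subjects")
  subjects <- sort(names(rppg_pools))
  fp_pre <- fingerprint_weights(model)
  nl <- length(model$layers)
  head0 <- model$layers[[nl]]

  # frozen-body features computed once per subject
  feats <- lapply(rppg_pools[subjects], function(p)
    model_features(model, p$x))
  ys <- lapply(rppg_pools[subjects], function(p) unname(p$y))

  results <- list()
  for (k in seq_along(subjects)) {
    test_s <- subjects[k]
    val_s <- subjects[if (k == length(subjects)) 1L else k + 1L]
    train_s <- setdiff(subjects, c(test_s, val_s))

    pool_t <- rppg_pools[[test_s]]
    nt <- pool_size(pool_t)
    ord <- order(pool_t$offset)
    n20 <- ceiling(0.2 * nt)
    first20 <- ord[seq_len(n20)]
    rand20 <- with_seed(derive_seed(train_cfg$seed, test_s),
                        sort(sample(ord, n20)))
    test_idx <- setdiff(ord, union(first20, rand20))
    extra_idx <- switch(cfg$personalization,
                        none = integer(0),
                        first_20 = first20,
                        random_20 = rand20)

    feat_tr <- do.call(rbind, feats[train_s])
    y_tr <- do.call(rbind, ys[train_s])
    if (length(extra_idx)) {
      ft <- feats[[test_s]]
      feat_tr <- rbind(feat_tr, ft[extra_idx, , drop = FALSE])
      y_tr <- rbind(y_tr, ys[[test_s]][extra_idx, , drop = FALSE])
    }
    feat_va <- feats[[val_s]]
    y_va <- ys[[val_s]]
    feat_te <- feats[[test_s]][test_idx, , drop = FALSE]
    y_te <- ys[[test_s]][test_idx, , drop = FALSE]

    pred_pre <- layer_forward(head0, feat_te)$out
    head_k <- with_seed(derive_seed(train_cfg$seed, paste0("fold", k)),
                        fit_head_on_features(head0, feat_tr, y_tr,
                                             feat_va, y_va, train_cfg))
    pred_post <- layer_forward(head_k, feat_te)$out
    results[[k]] <- data.frame(
      subject = test_s, val_subject = val_s,
      scenario = cfg$personalization, n_test = length(test_idx),
      mae_sbp_pre = mean(abs(pred_pre[, 1] - y_te[, 1])),
      mae_dbp_pre = mean(abs(pred_pre[, 2] - y_te[, 2])),
      mae_sbp_post = mean(abs(pred_post[, 1] - y_te[, 1])),
      mae_dbp_post = mean(abs(pred_post[, 2] - y_te[, 2])))
  }
  fp_post <- fingerprint_weights(model)
  if (!identical(fp_pre, fp_post)) {
    stop("freeze contract violated: non-final-layer weights changed")
  }
  list(results = do.call(rbind, results),
       fingerprints = c(pre = fp_pre, post = fp_post))
}

# --- window-length study harness -------------------------------------------

#' Window-parameterization study
#'
#' Trains each architecture on datasets built under both cropping strategies
#' for each window length, with repeated runs, and tabulates the test MAE
#' per cell. The resulting table feeds the paired comparison (same
#' architecture, length and repetition index across strategies) consumed by
#' [compare_error_distributions()].
#'
#' @param records List of [wave_record()]s (subject affiliation is ignored:
#'   splits are random, matching a record pool without subject identity).
#' @param architectures Character vector of architecture names.
#' @param lengths Window lengths (seconds / beat counts).
#' @param strategies Cropping strategies to compare.
#' @param repetitions Training repetitions per cell.
#' @param hyperparams Hyperparameter list passed to every model.
#' @param cfg A [training_config()] (the study convention is a 50-epoch
#'   budget).
#' @param snr_threshold SNR gate in dB.
#' @return Data frame with one row per
#'   (architecture, strategy, length, repetition): test MAE for SBP/DBP.
#' @export
run_window_study <- function(records, architectures = c("alexnet1d",
                                                        "resnet1d"),
                             lengths = c(5, 7), strategies = c("const_time",
                                                               "const_beats"),
                             repetitions = 3, hyperparams = list(),
                             cfg = training_config(max_epochs = 50),
                             snr_threshold = -7) {
  out <- list()
  for (strategy in strategies) for (len in lengths) {
    wcfg <- suppressWarnings(windowing_config(strategy, len))
    pairs <- lapply(records, function(r) {
      ws <- preprocess_record(r, wcfg, snr_threshold)
      if (!n_windows(ws)) return(NULL)
      labs <- label_windows(ws)
      filter_labelled_windows(ws, labs)
    })
    pairs <- Filter(Negate(is.null), pairs)
    pool <- build_pool(pairs)
    for (arch in architectures) for (rep_i in seq_len(repetitions)) {
      seed_i <- derive_seed(cfg$seed,
                            paste(strategy, len, arch, rep_i, sep = "|"))
      split <- split_mixed(pool, seed = seed_i)
      ms <- model_spec(arch, input_length = dim(ensure_3d(pool$x))[2],
                       input_channels = dim(ensure_3d(pool$x))[3],
                       hyperparams = hyperparams, seed = seed_i)
      cfg_i <- cfg; cfg_i$seed <- seed_i
      fit <- train_model(build_model(ms), split, cfg_i)
      pred <- predict_bp(fit$model, split$test$x)
      out[[length(out) + 1L]] <- data.frame(
        architecture = arch, strategy = strategy, length = len,
        repetition = rep_i,
        mae_sbp = mean(abs(pred[, 1] - split$test$y[, 1])),
        mae_dbp = mean(abs(pred[, 2] - split$test$y[, 2])))
    }
  }
  do.call(rbind, out)
}
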