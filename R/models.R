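#' Architecture zoo for scalar SBP/DBP regression
#'
#' Five registered architectures: 1-D adaptations of AlexNet and ResNet-18,
#' a spectro-temporal network (parallel time-domain and log-spectrogram
#' branches feeding a GRU), a CNN-biLSTM, and a constant mean regressor
#' baseline. Every network ends in a two-neuron linear regression head
#' (SBP, DBP). Channel counts follow the originals; a `width` hyperparameter
#' scales them down for desk-scale experiments. Normalization layers are
#' omitted: at the batch and depth scales this engine targets, residual
#' blocks with He initialization train stably without them.
#'
#' @name ppgbp-models
NULL

#' Model specification
#'
#' @param architecture One of `"alexnet1d"`, `"resnet1d"`,
#'   `"spectrotemporal"`, `"cnn_lstm"`, `"mean_regressor"`.
#' @param input_length Window length in samples.
#' @param input_channels 1 (raw) or 3 (raw + first/second derivative).
#' @param hyperparams Architecture-specific overrides (see details of
#'   [build_model()]).
#' @param seed Seed for parameter initialization.
#' @return A list of class `bp_model_spec`.
#' @export
model_spec <- function(architecture = c("alexnet1d", "resnet1d",
                                        "spectrotemporal", "cnn_lstm",
                                        "mean_regressor"),
                       input_length, input_channels = 1,
                       hyperparams = list(), seed = 1L) {
  architecture <- match.arg(architecture)
  stopifnot_scalar_pos(input_length, "input_length")
  if (!input_channels %in% c(1, 3)) stop("`input_channels` must be 1 or 3")
  structure(list(architecture = architecture,
                 input_length = as.integer(input_length),
                 input_channels = as.integer(input_channels),
                 hyperparams = hyperparams, seed = as.integer(seed)),
            class = "bp_model_spec")
}

hp_get <- function(hp, name, default) hp[[name]] %||% default

build_alexnet1d <- function(spec) {
  hp <- spec$hyperparams
  w <- hp_get(hp, "width", 1)
  f <- pmax(4L, round(w * c(96, 256, 384, 384, 256)))
  dense_units <- pmax(8L, round(w * hp_get(hp, "dense", c(4096, 4096))))
  drop_p <- hp_get(hp, "dropout", 0.5)
  t_len <- spec$input_length
  layers <- list()
  add <- function(l, new_t = NULL) {
    layers[[length(layers) + 1L]] <<- l
    if (!is.null(new_t)) t_len <<- new_t
  }
  add(nn_conv1d(spec$input_channels, f[1], 11, stride = 4, pad = 2),
      conv_out_len(t_len, 11, 4, 2))
  add(nn_relu())
  add(nn_maxpool(3, 2), conv_out_len(t_len, 3, 2, 0))
  add(nn_conv1d(f[1], f[2], 5, pad = 2), conv_out_len(t_len, 5, 1, 2))
  add(nn_relu())
  add(nn_maxpool(3, 2), conv_out_len(t_len, 3, 2, 0))
  add(nn_conv1d(f[2], f[3], 3, pad = 1), conv_out_len(t_len, 3, 1, 1))
  add(nn_relu())
  add(nn_conv1d(f[3], f[4], 3, pad = 1), conv_out_len(t_len, 3, 1, 1))
  add(nn_relu())
  add(nn_conv1d(f[4], f[5], 3, pad = 1), conv_out_len(t_len, 3, 1, 1))
  add(nn_relu())
  add(nn_maxpool(3, 2), conv_out_len(t_len, 3, 2, 0))
  add(nn_flatten())
  d_in <- t_len * f[5]
  for (du in dense_units) {
    add(nn_dense(d_in, du))
    add(nn_relu())
    add(nn_dropout(drop_p))
    d_in <- du
  }
  add(nn_dense(d_in, 2, is_head = TRUE))
  layers
}

resnet_block <- function(in_ch, out_ch, stride) {
  branch <- list(nn_conv1d(in_ch, out_ch, 3, stride = stride, pad = 1),
                 nn_relu(),
                 nn_conv1d(out_ch, out_ch, 3, stride = 1, pad = 1))
  shortcut <- if (stride != 1 || in_ch != out_ch) {
    nn_conv1d(in_ch, out_ch, 1, stride = stride, pad = 0)
  } else NULL
  nn_residual(branch, shortcut)
}

build_resnet1d <- function(spec) {
  hp <- spec$hyperparams
  w <- hp_get(hp, "width", 1)
  chans <- pmax(4L, round(w * c(64, 128, 256, 512)))
  blocks <- hp_get(hp, "blocks_per_stage", c(2, 2, 2, 2))
  layers <- list(
    nn_conv1d(spec$input_channels, chans[1], 7, stride = 2, pad = 3),
    nn_relu(),
    nn_maxpool(3, 2))
  in_ch <- chans[1]
  for (s in seq_along(chans)) {
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1 && s > 1) 2 else 1
      layers[[length(layers) + 1L]] <- resnet_block(in_ch, chans[s], stride)
      in_ch <- chans[s]
    }
  }
  layers[[length(layers) + 1L]] <- nn_gap()
  layers[[length(layers) + 1L]] <- nn_dense(in_ch, 2, is_head = TRUE)
  layers
}

build_cnn_lstm <- function(spec) {
  hp <- spec$hyperparams
  cf <- hp_get(hp, "conv_filters", 32)
  kernel <- hp_get(hp, "kernel", 5)
  stride <- hp_get(hp, "stride", 1)
  units <- hp_get(hp, "lstm_units", c(64, 64, 32))
  dense_units <- hp_get(hp, "dense_units", 128)
  bidir <- hp_get(hp, "bidirectional", TRUE)
  layers <- list(
    nn_conv1d(spec$input_channels, cf, kernel, stride = stride,
              pad = kernel %/% 2),
    nn_relu())
  in_ch <- cf
  for (i in seq_along(units)) {
    last <- i == length(units)
    layers[[length(layers) + 1L]] <-
      nn_lstm(in_ch, units[i], bidirectional = bidir, return_seq = !last)
    in_ch <- units[i] * (if (bidir) 2 else 1)
  }
  layers[[length(layers) + 1L]] <- nn_dense(in_ch, dense_units)
  layers[[length(layers) + 1L]] <- nn_relu()
  layers[[length(layers) + 1L]] <- nn_dense(dense_units, 2, is_head = TRUE)
  layers
}

build_spectrotemporal <- function(spec) {
  hp <- spec$hyperparams
  tf <- hp_get(hp, "temporal_filters", c(16, 32))
  sf <- hp_get(hp, "spec_filters", 16)
  gru_units <- hp_get(hp, "gru_units", 32)
  dense_units <- hp_get(hp, "dense_units", 32)
  nfft <- hp_get(hp, "nfft", 64)
  hop <- hp_get(hp, "hop", 32)
  t_len <- spec$input_length
  branch_a <- list(
    nn_conv1d(spec$input_channels, tf[1], 7, stride = 2, pad = 3),
    nn_relu(),
    resnet_block(tf[1], tf[1], 1),
    nn_conv1d(tf[1], tf[2], 5, stride = 2, pad = 2),
    nn_relu(),
    resnet_block(tf[2], tf[2], 1))
  t_a <- conv_out_len(t_len, 7, 2, 3)
  t_a <- conv_out_len(t_a, 5, 2, 2)
  n_frames <- floor((t_len - nfft) / hop) + 1
  nb <- nfft %/% 2 + 1
  branch_b <- list(
    nn_conv1d(nb, sf, 3, stride = 1, pad = 1),
    nn_relu(),
    nn_interp(n_frames, t_a))
  list(
    nn_two_branch(branch_a, branch_b, nfft, hop),
    nn_gru(tf[2] + sf, gru_units, return_seq = FALSE),
    nn_dense(gru_units, dense_units),
    nn_relu(),
    nn_dense(dense_units, 2, is_head = TRUE))
}

#' Build a model from its specification
#'
#' Parameter initialization is fully seeded. Hyperparameters per
#' architecture: `alexnet1d` and `resnet1d` accept `width` (channel
#' multiplier); `cnn_lstm` accepts `conv_filters` (32), `kernel` (5),
#' `stride` (1), `lstm_units` (64, 64, 32 per direction), `dense_units`
#' (128) and `bidirectional`; `spectrotemporal` accepts `temporal_filters`,
#' `spec_filters`, `gru_units`, `dense_units`, `nfft`, `hop`.
#'
#' @param spec A [model_spec()].
#' @return An object of class `bp_model` (or `bp_mean_regressor_spec` for
#'   the baseline, which must be fitted with [mean_regressor_fit()]).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "bp_model_spec"))
  if (spec$architecture == "mean_regressor") {
    stop("the mean regressor is fitted with mean_regressor_fit(), not built")
  }
  layers <- with_seed(spec$seed, switch(spec$architecture,
    alexnet1d = build_alexnet1d(spec),
    resnet1d = build_resnet1d(spec),
    cnn_lstm = build_cnn_lstm(spec),
    spectrotemporal = build_spectrotemporal(spec)))
  structure(list(spec = spec, layers = layers, trained = FALSE,
                 train_window_ids = character()),
            class = "bp_model")
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<bp_model> %s: input %d x %d, %d top-level layers%s\n",
              x$spec$architecture, x$spec$input_length,
              x$spec$input_channels, length(x$layers),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Layer inventory of a model
#'
#' @param model A `bp_model`.
#' @return Data frame with one row per top-level layer: type and its main
#'   size attribute (filters/units for conv, recurrent and dense layers).
#' @export
model_layer_inventory <- function(model) {
  rows <- lapply(model$layers, function(l) {
    size <- switch(l$type,
      conv1d = l$out_ch, dense = l$out_dim, lstm = l$hidden,
      gru = l$hidden, NA_integer_)
    data.frame(type = l$type, size = size,
               kernel = if (l$type == "conv1d") l$kernel else NA_integer_,
               stride = if (l$type == "conv1d") l$stride else NA_integer_,
               is_head = isTRUE(l$is_head))
  })
  do.call(rbind, rows)
}

#' Predict SBP/DBP for a batch of windows
#'
#' @param model A `bp_model` or fitted mean regressor.
#' @param x Window matrix `(n, samples)` or array `(n, samples, channels)`.
#' @param batch_size Forward-pass batch size.
#' @return Numeric matrix `(n, 2)` with columns `sbp`, `dbp`.
#' @export
predict_bp <- function(model, x, batch_size = 256) {
  UseMethod("predict_bp")
}

#' @export
predict_bp.bp_model <- function(model, x, batch_size = 256) {
  x <- ensure_3d(x)
  n <- dim(x)[1]
  out <- matrix(0, n, 2, dimnames = list(NULL, c("sbp", "dbp")))
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    out[idx, ] <- nn_forward(model$layers, x[idx, , , drop = FALSE],
                             train = FALSE)$out
    at <- at + batch_size
  }
  out
}

#' Forward pass up to (but excluding) the regression head
#'
#' Used by the transfer protocol: with all non-final layers frozen, head
#' optimization is a small regression on these cached features.
#'
#' @param model A `bp_model` whose last layer is the head.
#' @param x Input windows.
#' @param batch_size Forward-pass batch size.
#' @return Feature matrix `(n, d)`.
#' @export
model_features <- function(model, x, batch_size = 256) {
  x <- ensure_3d(x)
  nl <- length(model$layers)
  if (!isTRUE(model$layers[[nl]]$is_head)) {
    stop("last layer is not the regression head")
  }
  body <- model$layers[-nl]
  n <- dim(x)[1]
  out <- NULL
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    o <- nn_forward(body, x[idx, , , drop = FALSE], train = FALSE)$out
    if (is.null(out)) out <- matrix(0, n, ncol(o))
    out[idx, ] <- o
    at <- at + batch_size
  }
  out
}

# --- weight state and fingerprints -----------------------------------------

collect_layer_params <- function(layer) {
  if (layer$type == "residual") {
    out <- lapply(layer$branch, collect_layer_params)
    if (!is.null(layer$shortcut)) {
      out <- c(out, list(collect_layer_params(layer$shortcut)))
    }
    return(out)
  }
  if (layer$type == "two_branch") {
    return(list(a = lapply(layer$branch_a, collect_layer_params),
                b = lapply(layer$branch_b, collect_layer_params)))
  }
  layer$params
}

#' Named weight state of a model
#'
#' @param model A `bp_model`.
#' @param exclude_head Drop the regression-head parameters.
#' @return Nested list of parameter arrays.
#' @export
get_weight_state <- function(model, exclude_head = FALSE) {
  layers <- model$layers
  if (exclude_head) {
    layers <- Filter(function(l) !isTRUE(l$is_head), layers)
  }
  lapply(layers, collect_layer_params)
}

#' Fingerprint of all non-head weights
#'
#' MD5 digest of the serialized non-final-layer parameters; bit-identical
#' weights give identical fingerprints, so the transfer protocol's freeze
#' contract can be asserted exactly.
#'
#' @param model A `bp_model`.
#' @return Character MD5 string.
#' @export
fingerprint_weights <- function(model) {
  ws <- get_weight_state(model, exclude_head = TRUE)
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  saveRDS(ws, tf, compress = FALSE, version = 2)
  unname(tools::md5sum(tf))
}

# --- mean regressor ---------------------------------------------------------

#' Fit the mean-regressor baseline
#'
#' Predicts the training-set mean SBP and DBP for every input. Its test MAE
#' is by construction the mean absolute deviation of the test labels from
#' the training means.
#'
#' @param train_labels Data frame with `sbp`/`dbp` columns, or a two-column
#'   matrix.
#' @return An object of class `bp_mean_regressor`.
#' @export
mean_regressor_fit <- function(train_labels) {
  y <- if (is.matrix(train_labels)) train_labels
       else cbind(sbp = train_labels$sbp, dbp = train_labels$dbp)
  if (!nrow(y)) stop("training labels are empty")
  structure(list(mean_sbp = mean(y[, 1]), mean_dbp = mean(y[, 2])),
            class = "bp_mean_regressor")
}

#' @export
predict_bp.bp_mean_regressor <- function(model, x, batch_size = 256) {
  n <- if (is.null(dim(x))) length(x) else dim(x)[1]
  cbind(sbp = rep(model$mean_sbp, n), dbp = rep(model$mean_dbp, n))
}
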