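#' Evaluation: overall and bin-wise error, baselines, significance
#'
#' Errors are reported as mean absolute error (MAE) in mmHg, overall and in
#' 10 mmHg bins spanning the plausible label ranges, against a
#' mean-regressor baseline, with Kolmogorov-Smirnov / paired t comparisons
#' and a BHS-style within-10 mmHg grade.
#'
#' @name ppgbp-evaluation
NULL

#' Mean absolute error per target
#'
#' @param predictions Matrix `(n, 2)` of predicted (SBP, DBP).
#' @param labels Matrix `(n, 2)` or data frame with `sbp`/`dbp` columns.
#' @return Named vector `c(mae_sbp, mae_dbp)` in mmHg.
#' @export
mae <- function(predictions, labels) {
  y <- if (is.matrix(labels)) labels else cbind(labels$sbp, labels$dbp)
  if (!nrow(y)) stop("empty input")
  if (nrow(predictions) != nrow(y)) stop("length mismatch")
  c(mae_sbp = mean(abs(predictions[, 1] - y[, 1])),
    mae_dbp = mean(abs(predictions[, 2] - y[, 2])))
}

#' Bin-wise mean absolute error
#'
#' Samples are assigned to bins by their true label; bins are half-open
#' `[low, high)` anchored at the lower plausibility bound, with the final
#' bin closed so every sample in range falls into exactly one bin. Empty
#' bins are reported with a count of zero and `NA` MAE (they never
#' propagate into aggregates).
#'
#' @param predicted Numeric vector of predictions for one target.
#' @param true Numeric vector of true labels for the same target.
#' @param range Label range spanned by the bins (e.g. `c(75, 165)` for SBP).
#' @param bin_width Bin width in mmHg (default 10).
#' @return Data frame with `bin_lo`, `bin_hi`, `n`, `mae`.
#' @export
binwise_mae <- function(predicted, true, range, bin_width = 10) {
  if (bin_width <= 0) stop("`bin_width` must be positive")
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  nb <- length(edges) - 1L
  bin <- findInterval(true, edges, rightmost.closed = TRUE)
  bin[bin < 1 | bin > nb] <- NA
  err <- abs(predicted - true)
  data.frame(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    n = vapply(seq_len(nb), function(b) sum(bin == b, na.rm = TRUE), 0L),
    mae = vapply(seq_len(nb), function(b) {
      idx <- which(bin == b)
      if (length(idx)) mean(err[idx]) else NA_real_
    }, 0))
}

#' Compare two error distributions
#'
#' `two_sample_ks` applies a two-sample Kolmogorov-Smirnov test to the two
#' per-window absolute-error samples; `paired_t` applies a paired t-test
#' (pairing unit: matched cells such as the same architecture, window
#' length and repetition index). A paired design with zero-variance
#' differences is degenerate rather than an error: a constant nonzero
#' difference is reported as perfectly separated (infinite statistic,
#' p = 0), an all-zero difference as no effect (statistic 0, p = 1).
#'
#' @param errors_a,errors_b Numeric samples (equal length for the paired
#'   design).
#' @param design `"two_sample_ks"` or `"paired_t"`.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `bp_comparison` with `design`, `statistic`,
#'   `p_value`, `alpha`, `significant` and an optional `note`.
#' @export
compare_error_distributions <- function(errors_a, errors_b,
                                        design = c("two_sample_ks",
                                                   "paired_t"),
                                        alpha = 0.05) {
  design <- match.arg(design)
  if (length(errors_a) < 2 || length(errors_b) < 2) {
    stop("need at least 2 observations per group")
  }
  note <- NULL
  if (design == "two_sample_ks") {
    ht <- suppressWarnings(stats::ks.test(errors_a, errors_b))
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    if (length(errors_a) != length(errors_b)) {
      stop("paired design requires equal lengths")
    }
    d <- errors_a - errors_b
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        statistic <- 0; p <- 1
        note <- "degenerate: all paired differences zero"
      } else {
        statistic <- sign(mean(d)) * Inf; p <- 0
        note <- "degenerate: constant nonzero paired difference"
      }
    } else {
      ht <- stats::t.test(errors_a, errors_b, paired = TRUE)
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  }
  structure(list(design = design, statistic = statistic, p_value = p,
                 alpha = alpha, significant = p < alpha, note = note),
            class = "bp_comparison")
}

#' @export
print.bp_comparison <- function(x, ...) {
  cat(sprintf("<bp_comparison> %s: statistic %.4g, p %.4g (%ssignificant at %.2g)\n",
              x$design, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' BHS-style grade: fraction of errors under 10 mmHg
#'
#' @param errors Absolute errors in mmHg.
#' @param threshold_mmHg Acceptable-error bound (default 10).
#' @param pass_fraction Required fraction (default 0.85).
#' @return List with `proportion_within` and logical `pass`
#'   (`proportion_within > pass_fraction`).
#' @export
bhs_grade <- function(errors, threshold_mmHg = 10, pass_fraction = 0.85) {
  if (!length(errors)) stop("empty input")
  p <- mean(abs(errors) < threshold_mmHg)
  list(proportion_within = p, pass = p > pass_fraction)
}

#' Build a full evaluation report
#'
#' @param predictions Matrix `(n, 2)` of predicted (SBP, DBP).
#' @param labels Matrix or data frame of true labels.
#' @param baseline A fitted [mean_regressor_fit()] for the baseline row, or
#'   `NULL`.
#' @param sbp_range,dbp_range Bin ranges in mmHg.
#' @param bin_width Bin width in mmHg.
#' @return A list of class `bp_evaluation_report`: overall MAE, bin tables,
#'   baseline MAE, BHS grades and the sample count. The count-weighted mean
#'   of the bin MAEs equals the overall MAE by construction, asserted to
#'   1e-9.
#' @export
evaluation_report <- function(predictions, labels, baseline = NULL,
                              sbp_range = c(75, 165), dbp_range = c(40, 80),
                              bin_width = 10) {
  y <- if (is.matrix(labels)) labels else cbind(sbp = labels$sbp,
                                                dbp = labels$dbp)
  overall <- mae(predictions, y)
  bins_sbp <- binwise_mae(predictions[, 1], y[, 1], sbp_range, bin_width)
  bins_dbp <- binwise_mae(predictions[, 2], y[, 2], dbp_range, bin_width)
  for (tb in list(list(bins_sbp, overall[1], 1),
                  list(bins_dbp, overall[2], 2))) {
    b <- tb[[1]]
    in_bins <- sum(b$n)
    if (in_bins == nrow(y)) {
      agg <- sum(b$n * b$mae, na.rm = TRUE) / in_bins
      if (abs(agg - tb[[2]]) > 1e-9) {
        stop("bin-weighted MAE does not aggregate to the overall MAE")
      }
    }
  }
  baseline_mae <- if (is.null(baseline)) c(mae_sbp = NA_real_,
                                           mae_dbp = NA_real_)
                  else mae(predict_bp(baseline, y), y)
  structure(list(
    overall_mae_sbp = unname(overall[1]),
    overall_mae_dbp = unname(overall[2]),
    bin_width = bin_width,
    bins_sbp = bins_sbp, bins_dbp = bins_dbp,
    baseline_mae_sbp = unname(baseline_mae[1]),
    baseline_mae_dbp = unname(baseline_mae[2]),
    bhs_sbp = bhs_grade(predictions[, 1] - y[, 1]),
    bhs_dbp = bhs_grade(predictions[, 2] - y[, 2]),
    n_test = nrow(y)),
    class = "bp_evaluation_report")
}

#' @export
print.bp_evaluation_report <- function(x, ...) {
  cat(sprintf("<bp_evaluation_report> n = %d\n", x$n_test))
  cat(sprintf("  MAE: SBP %.2f mmHg, DBP %.2f mmHg\n",
              x$overall_mae_sbp, x$overall_mae_dbp))
  if (is.finite(x$baseline_mae_sbp)) {
    cat(sprintf("  mean-regressor baseline: SBP %.2f, DBP %.2f mmHg\n",
                x$baseline_mae_sbp, x$baseline_mae_dbp))
  }
  cat(sprintf("  within 10 mmHg: SBP %.1f%%, DBP %.1f%% (BHS pass: %s / %s)\n",
              100 * x$bhs_sbp$proportion_within,
              100 * x$bhs_dbp$proportion_within,
              x$bhs_sbp$pass, x$bhs_dbp$pass))
  invisible(x)
}

#' Serialize / restore an evaluation report
#'
#' Reports round-trip through JSON without loss.
#'
#' @param report A `bp_evaluation_report`.
#' @param path File path.
#' @return `write_report` returns the path; `read_report` the restored
#'   report.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "bp_evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$bins_sbp <- as.data.frame(obj$bins_sbp)
  obj$bins_dbp <- as.data.frame(obj$bins_dbp)
  obj$n_test <- as.integer(obj$n_test)
  structure(obj, class = "bp_evaluation_report")
}
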