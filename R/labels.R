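#' Ground-truth labels from ABP segments
#'
#' Systolic/diastolic ground truth is the median of per-beat ABP extrema
#' within a window; the heart rate used for the plausibility rule is derived
#' from the ABP inter-peak intervals so that the label never depends on PPG
#' quality.
#'
#' @name ppgbp-labels
NULL

#' Plausibility ranges for labels
#'
#' Windows whose label falls outside these inclusive ranges are rejected:
#' systolic 75-165 mmHg, diastolic 40-80 mmHg, heart rate 50-140 beats/min.
#'
#' @param sbp_range,dbp_range Pressure ranges in mmHg.
#' @param hr_range Heart-rate range in beats/min.
#' @return A list of class `bp_plausibility_config`.
#' @export
plausibility_config <- function(sbp_range = c(75, 165),
                                dbp_range = c(40, 80),
                                hr_range = c(50, 140)) {
  for (r in list(sbp_range, dbp_range, hr_range)) {
    if (length(r) != 2L || r[1] >= r[2]) stop("each range needs low < high")
  }
  structure(list(sbp_range = sbp_range, dbp_range = dbp_range,
                 hr_range = hr_range),
            class = "bp_plausibility_config")
}

# Local maxima with a minimum inter-peak distance and a prominence floor.
find_peaks <- function(x, min_distance, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lhs <- x[1:i]
    hi_l <- which(lhs > x[i])
    left_base <- if (length(hi_l)) min(x[(max(hi_l)):i]) else min(lhs)
    rhs <- x[i:n]
    hi_r <- which(rhs > x[i])
    right_base <- if (length(hi_r)) min(rhs[1:min(hi_r)]) else min(rhs)
    x[i] - max(left_base, right_base)
  }, 0)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  ord <- order(x[cand], decreasing = TRUE)
  taken <- integer(0)
  for (j in ord) {
    if (!length(taken) || all(abs(cand[j] - taken) >= min_distance)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  sort(cand[keep])
}

#' Detect systolic peaks and diastolic troughs in an ABP segment
#'
#' Systolic peaks are local maxima passing a minimum inter-peak distance of
#' half the expected beat period and a prominence of at least 10% of the
#' segment's amplitude range; diastolic troughs are the minima between
#' consecutive systolic peaks.
#'
#' @param abp Numeric ABP segment in mmHg.
#' @param fs Sampling rate in Hz.
#' @param hr_hint Expected heart rate in beats/min (sets the distance rule).
#' @return A list with data frames `systolic` and `diastolic`
#'   (columns `index`, `value`) and a logical `too_few_peaks`.
#' @export
detect_abp_extrema <- function(abp, fs, hr_hint = 75) {
  if (!is.finite(hr_hint) || hr_hint <= 0) hr_hint <- 75
  min_dist <- max(1, round(0.5 * (60 / hr_hint) * fs))
  min_prom <- 0.1 * diff(range(abp))
  sys_idx <- find_peaks(abp, min_dist, min_prom)
  too_few <- length(sys_idx) < 2L
  dia_idx <- integer(0)
  if (!too_few) {
    dia_idx <- vapply(seq_len(length(sys_idx) - 1L), function(k) {
      span <- (sys_idx[k] + 1L):(sys_idx[k + 1L] - 1L)
      span[which.min(abp[span])]
    }, 0L)
  }
  list(systolic = data.frame(index = sys_idx, value = abp[sys_idx]),
       diastolic = data.frame(index = dia_idx, value = abp[dia_idx]),
       too_few_peaks = too_few)
}

#' Label one window from its ABP segment
#'
#' SBP/DBP are the medians of the detected systolic peak / diastolic trough
#' values; the median heart rate comes from the inter-systolic-peak
#' intervals. Plausibility bounds are inclusive and checked in the order
#' systolic, diastolic, heart rate: a window violating several rules is
#' flagged with the first.
#'
#' @param abp Numeric ABP segment in mmHg.
#' @param fs Sampling rate in Hz.
#' @param cfg A [plausibility_config()].
#' @param hr_hint Heart-rate hint for the peak detector, beats/min.
#' @return A one-row data frame of class `bp_label` with columns `sbp`,
#'   `dbp`, `median_hr`, `n_systolic_peaks`, `valid`, `reject_reason`.
#' @export
label_window <- function(abp, fs, cfg = plausibility_config(), hr_hint = 75) {
  ex <- detect_abp_extrema(abp, fs, hr_hint)
  if (ex$too_few_peaks || nrow(ex$diastolic) < 1L) {
    return(new_bp_label(NA_real_, NA_real_, NA_real_,
                        nrow(ex$systolic), FALSE, "too_few_peaks"))
  }
  sbp <- stats::median(ex$systolic$value)
  dbp <- stats::median(ex$diastolic$value)
  intervals <- diff(ex$systolic$index) / fs
  median_hr <- stats::median(60 / intervals)
  reason <- check_plausibility(sbp, dbp, median_hr, cfg)
  new_bp_label(sbp, dbp, median_hr, nrow(ex$systolic),
               reason == "none", reason)
}

#' Apply the plausibility rules to label values
#'
#' Bounds are inclusive and rules are checked in the order systolic,
#' diastolic, heart rate: the first violated rule names the rejection. A
#' non-finite heart rate skips the heart-rate rule (used for reference-BP
#' labels without a usable rate estimate).
#'
#' @param sbp,dbp Pressures in mmHg (vectorized).
#' @param median_hr Heart rate in beats/min (vectorized).
#' @param cfg A [plausibility_config()].
#' @return Character vector: `"none"` for plausible labels, otherwise the
#'   first violated rule (`"sbp_range"`, `"dbp_range"`, `"hr_range"`).
#' @export
check_plausibility <- function(sbp, dbp, median_hr,
                               cfg = plausibility_config()) {
  reason <- rep("none", length(sbp))
  hr_bad <- is.finite(median_hr) &
    (median_hr < cfg$hr_range[1] | median_hr > cfg$hr_range[2])
  reason[hr_bad] <- "hr_range"
  dbp_bad <- dbp < cfg$dbp_range[1] | dbp > cfg$dbp_range[2]
  reason[dbp_bad] <- "dbp_range"
  sbp_bad <- sbp < cfg$sbp_range[1] | sbp > cfg$sbp_range[2]
  reason[sbp_bad] <- "sbp_range"
  reason
}

new_bp_label <- function(sbp, dbp, median_hr, n_peaks, valid, reason) {
  structure(data.frame(sbp = sbp, dbp = dbp, median_hr = median_hr,
                       n_systolic_peaks = n_peaks, valid = valid,
                       reject_reason = reason, stringsAsFactors = FALSE),
            class = c("bp_label", "data.frame"))
}

#' Label every window of a set from its ABP segments
#'
#' @param ws A window set whose ABP segments are present.
#' @param cfg A [plausibility_config()].
#' @return A data frame with one `bp_label` row per window.
#' @export
label_windows <- function(ws, cfg = plausibility_config()) {
  stopifnot(inherits(ws, "bp_window_set"))
  rows <- lapply(seq_len(n_windows(ws)), function(i) {
    seg <- ws$abp[[i]]
    if (is.null(seg)) stop("window set carries no ABP segments")
    hint <- ws$meta$estimated_hr[i]
    label_window(seg, ws$abp_fs, cfg,
                 hr_hint = if (is.finite(hint)) hint else 75)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label rPPG windows from a minute-grid reference series
#'
#' Each window takes the reference SBP/DBP at the minute mark nearest to its
#' source-time center; plausibility bounds are applied as for ABP-derived
#' labels (the heart-rate rule uses the window's spectral estimate since no
#' ABP is available for camera data).
#'
#' @param ws A window set cropped from a POS pulse series.
#' @param reference Data frame with columns `time_s`, `sbp`, `dbp`.
#' @param cfg A [plausibility_config()].
#' @return A data frame of label rows.
#' @export
label_windows_from_reference <- function(ws, reference,
                                         cfg = plausibility_config()) {
  stopifnot(inherits(ws, "bp_window_set"))
  rows <- lapply(seq_len(n_windows(ws)), function(i) {
    centre <- (ws$meta$source_offset[i] + ws$meta$span[i] / 2) / ws$abp_fs
    j <- which.min(abs(reference$time_s - centre))
    sbp <- reference$sbp[j]; dbp <- reference$dbp[j]
    hr <- ws$meta$estimated_hr[i]
    reason <- check_plausibility(sbp, dbp, hr, cfg)
    new_bp_label(sbp, dbp, hr, NA_integer_, reason == "none", reason)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep only validly labelled windows
#'
#' @param ws A window set.
#' @param labels The matching label data frame from [label_windows()].
#' @return A list with the filtered `windows` and `labels` plus a named
#'   `counts` vector of rejections per reason.
#' @export
filter_labelled_windows <- function(ws, labels) {
  stopifnot(inherits(ws, "bp_window_set"), nrow(labels) == n_windows(ws))
  keep <- which(labels$valid)
  reasons <- c("sbp_range", "dbp_range", "hr_range", "too_few_peaks")
  counts <- vapply(reasons,
                   function(r) sum(labels$reject_reason == r), 0L)
  list(windows = subset_window_set(ws, keep),
       labels = labels[keep, , drop = FALSE],
       counts = counts)
}
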