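#' Dataset construction
#'
#' A window pool collects labelled windows from many subjects; splits are
#' either subject-aware ("non-mixed": disjoint subject sets per partition)
#' or sample-level ("mixed": samples shuffled regardless of subject, which
#' leaks subject identity between train and test). All randomness flows from
#' a single split-level seed via deterministic per-subject derived seeds.
#'
#' @name ppgbp-datasets
NULL

#' Build a window pool from labelled window sets
#'
#' @param pairs List of `list(windows =, labels =)` entries, e.g. the output
#'   of [filter_labelled_windows()] per subject. Only valid labels may be
#'   present.
#' @return An object of class `bp_window_pool` with stacked inputs `x`,
#'   targets `y` (columns `sbp`, `dbp`), subject ids, source offsets and
#'   globally unique window ids `subject_id@offset`.
#' @export
build_pool <- function(pairs) {
  pairs <- Filter(function(p) n_windows(p$windows) > 0, pairs)
  if (!length(pairs)) stop("no windows to pool")
  xs <- lapply(pairs, function(p) p$windows$x)
  nc <- unique(vapply(xs, function(x)
    if (length(dim(x)) == 3L) dim(x)[3] else 1L, 0L))
  if (length(nc) != 1L) stop("inconsistent channel counts across subjects")
  x <- if (nc == 1L) do.call(rbind, xs) else {
    nr <- sum(vapply(xs, function(x) dim(x)[1], 0L))
    arr <- array(0, c(nr, dim(xs[[1]])[2], nc))
    at <- 1L
    for (xi in xs) {
      arr[at:(at + dim(xi)[1] - 1L), , ] <- xi
      at <- at + dim(xi)[1]
    }
    arr
  }
  y <- do.call(rbind, lapply(pairs, function(p)
    cbind(sbp = p$labels$sbp, dbp = p$labels$dbp)))
  subject <- unlist(lapply(pairs, function(p) p$windows$meta$subject_id))
  offset <- unlist(lapply(pairs, function(p) p$windows$meta$source_offset))
  structure(list(x = x, y = y, subject = subject, offset = offset,
                 id = paste0(subject, "@", offset)),
            class = "bp_window_pool")
}

#' @export
print.bp_window_pool <- function(x, ...) {
  cat(sprintf("<bp_window_pool> %d windows from %d subjects\n",
              length(x$subject), length(unique(x$subject))))
  invisible(x)
}

pool_size <- function(pool) length(pool$subject)

subset_pool <- function(pool, idx) {
  out <- pool
  out$x <- if (length(dim(pool$x)) == 3L) pool$x[idx, , , drop = FALSE]
           else pool$x[idx, , drop = FALSE]
  out$y <- pool$y[idx, , drop = FALSE]
  out$subject <- pool$subject[idx]
  out$offset <- pool$offset[idx]
  out$id <- pool$id[idx]
  out
}

#' Cap each subject's contribution to a pool
#'
#' Subjects with at most `cap` windows pass through intact; larger subjects
#' contribute a uniform random subset of exactly `cap` windows, drawn with a
#' per-subject seed derived from the given seed.
#'
#' @param pool A [build_pool()] result.
#' @param cap Maximum windows per subject (default 2000).
#' @param seed Integer seed.
#' @return The capped pool (original window order preserved).
#' @export
cap_subjects <- function(pool, cap = 2000, seed = 1L) {
  stopifnot(inherits(pool, "bp_window_pool"))
  if (cap <= 0) stop("`cap` must be positive")
  keep <- unlist(lapply(unique(pool$subject), function(s) {
    idx <- which(pool$subject == s)
    if (length(idx) <= cap) idx
    else with_seed(derive_seed(seed, s), sort(sample(idx, cap)))
  }))
  subset_pool(pool, sort(keep))
}

new_dataset_split <- function(mode, train, val, test, assignment, cap, seed) {
  for (pair in list(list(train, val), list(train, test), list(val, test))) {
    if (length(intersect(pair[[1]]$id, pair[[2]]$id))) {
      stop("partitions share windows; split is invalid")
    }
  }
  if (mode == "non_mixed") {
    subs <- list(unique(train$subject), unique(val$subject),
                 unique(test$subject))
    if (length(intersect(subs[[1]], subs[[2]])) ||
        length(intersect(subs[[1]], subs[[3]])) ||
        length(intersect(subs[[2]], subs[[3]]))) {
      stop("non-mixed split has overlapping subject sets")
    }
  }
  structure(list(mode = mode, train = train, val = val, test = test,
                 subject_assignment = assignment, per_subject_cap = cap,
                 seed = seed),
            class = "bp_dataset_split")
}

#' @export
print.bp_dataset_split <- function(x, ...) {
  cat(sprintf("<bp_dataset_split> mode %s: %d train / %d val / %d test windows\n",
              x$mode, pool_size(x$train), pool_size(x$val),
              pool_size(x$test)))
  invisible(x)
}

#' Subject-aware (non-mixed) split
#'
#' Subjects are randomly assigned to exactly one of train/validation/test
#' (surplus subjects are tagged `excluded`, never silently dropped); samples
#' are then drawn uniformly without replacement within each partition. If a
#' requested sample count exceeds what a partition holds, all counts are
#' scaled down proportionally with a warning.
#'
#' @param pool A capped [build_pool()] result.
#' @param n_train_subjects,n_val_subjects,n_test_subjects Subject counts.
#' @param n_train,n_val,n_test Optional sample counts per partition
#'   (default: everything available).
#' @param seed Integer seed.
#' @param cap The per-subject cap already applied (recorded in the split).
#' @return A `bp_dataset_split` with `mode = "non_mixed"`.
#' @export
split_non_mixed <- function(pool, n_train_subjects, n_val_subjects,
                            n_test_subjects, n_train = NULL, n_val = NULL,
                            n_test = NULL, seed = 1L, cap = 2000) {
  stopifnot(inherits(pool, "bp_window_pool"))
  subjects <- unique(pool$subject)
  need <- n_train_subjects + n_val_subjects + n_test_subjects
  if (need > length(subjects)) {
    stop(sprintf("requested %d subjects but pool has %d", need,
                 length(subjects)))
  }
  with_seed(seed, {
    perm <- sample(subjects)
    assign_train <- perm[seq_len(n_train_subjects)]
    assign_val <- perm[n_train_subjects + seq_len(n_val_subjects)]
    assign_test <- perm[n_train_subjects + n_val_subjects +
                          seq_len(n_test_subjects)]
    excluded <- setdiff(subjects, c(assign_train, assign_val, assign_test))
    assignment <- c(stats::setNames(rep("train", length(assign_train)), assign_train),
                    stats::setNames(rep("val", length(assign_val)), assign_val),
                    stats::setNames(rep("test", length(assign_test)), assign_test),
                    stats::setNames(rep("excluded", length(excluded)), excluded))
    take <- function(sub_ids, n_req) {
      idx <- which(pool$subject %in% sub_ids)
      if (!is.null(n_req) && n_req < length(idx)) {
        idx <- sort(sample(idx, n_req))
      } else if (!is.null(n_req) && n_req > length(idx)) {
        warning(sprintf("requested %d samples but only %d available; using all",
                        n_req, length(idx)))
      }
      subset_pool(pool, idx)
    }
    # proportional scale-down if any partition is over-requested
    reqs <- list(train = n_train, val = n_val, test = n_test)
    avail <- c(train = sum(pool$subject %in% assign_train),
               val = sum(pool$subject %in% assign_val),
               test = sum(pool$subject %in% assign_test))
    ratio <- 1
    for (p in names(reqs)) {
      if (!is.null(reqs[[p]]) && reqs[[p]] > avail[[p]]) {
        ratio <- min(ratio, avail[[p]] / reqs[[p]])
      }
    }
    if (ratio < 1) {
      warning(sprintf("sample counts scaled down by factor %.3g to fit pool",
                      ratio))
      reqs <- lapply(reqs, function(r) if (is.null(r)) NULL
                     else as.integer(floor(r * ratio)))
    }
    new_dataset_split("non_mixed",
                      take(assign_train, reqs$train),
                      take(assign_val, reqs$val),
                      take(assign_test, reqs$test),
                      assignment, cap, seed)
  })
}

#' Sample-level (mixed) split
#'
#' Chooses `n_subjects` subjects, pools their capped samples, shuffles them
#' ignoring subject identity, and cuts by the given fractions. Subjects with
#' many windows will almost surely appear on both sides of the train/test
#' boundary - this is the leakage condition the non-mixed split prevents.
#'
#' @param pool A capped [build_pool()] result.
#' @param n_subjects Number of subjects to include (default: all).
#' @param fractions Train/validation/test fractions summing to 1 (default
#'   2/3, 1/6, 1/6, mirroring a 1M/250k/250k sample ratio).
#' @param seed Integer seed.
#' @param cap The per-subject cap already applied (recorded in the split).
#' @return A `bp_dataset_split` with `mode = "mixed"`.
#' @export
split_mixed <- function(pool, n_subjects = NULL,
                        fractions = c(2 / 3, 1 / 6, 1 / 6), seed = 1L,
                        cap = 2000) {
  stopifnot(inherits(pool, "bp_window_pool"))
  if (abs(sum(fractions) - 1) > 1e-9) stop("`fractions` must sum to 1")
  subjects <- unique(pool$subject)
  with_seed(seed, {
    chosen <- if (is.null(n_subjects)) subjects
              else sample(subjects, min(n_subjects, length(subjects)))
    idx <- which(pool$subject %in% chosen)
    perm <- sample(idx)
    n <- length(perm)
    n_tr <- floor(fractions[1] * n)
    n_va <- floor(fractions[2] * n)
    tr <- perm[seq_len(n_tr)]
    va <- perm[n_tr + seq_len(n_va)]
    te <- perm[(n_tr + n_va + 1L):n]
    assignment <- stats::setNames(rep("mixed", length(chosen)), chosen)
    new_dataset_split("mixed", subset_pool(pool, tr), subset_pool(pool, va),
                      subset_pool(pool, te), assignment, cap, seed)
  })
}

#' Personalization partition for one subject
#'
#' Windows are ordered by source offset. The calibration set is either the
#' first 20% (`first_20`) or 20% drawn at random from the union of the first
#' 20% and the spare pool (`random_20`). The last 80% is split at its
#' midpoint: the first half is the spare pool, the second half is the test
#' set. The test set is identical for both strategies under a given seed.
#'
#' @param subject_pool A `bp_window_pool` restricted to one subject.
#' @param strategy `"first_20"` or `"random_20"`.
#' @param seed Integer seed (used by `random_20`).
#' @return A list of class `bp_personalization_partition` with pools
#'   `calibration`, `test`, `spare_pool` and the index sets used.
#' @export
make_personalization_partition <- function(subject_pool,
                                           strategy = c("first_20",
                                                        "random_20"),
                                           seed = 1L) {
  stopifnot(inherits(subject_pool, "bp_window_pool"))
  strategy <- match.arg(strategy)
  if (length(unique(subject_pool$subject)) != 1L) {
    stop("`subject_pool` must contain exactly one subject")
  }
  n <- pool_size(subject_pool)
  if (n < 10) stop("need at least 10 windows to personalize")
  ord <- order(subject_pool$offset)
  n20 <- ceiling(0.2 * n)
  first20 <- ord[seq_len(n20)]
  last80 <- ord[(n20 + 1L):n]
  m <- length(last80)
  spare <- last80[seq_len(floor(m / 2))]
  test <- last80[(floor(m / 2) + 1L):m]
  calib <- if (strategy == "first_20") first20 else {
    with_seed(derive_seed(seed, subject_pool$subject[1]),
              sort(sample(c(first20, spare), n20)))
  }
  if (length(intersect(calib, test))) stop("calibration and test overlap")
  structure(list(subject_id = subject_pool$subject[1], strategy = strategy,
                 calibration = subset_pool(subject_pool, calib),
                 test = subset_pool(subject_pool, test),
                 spare_pool = subset_pool(subject_pool, spare),
                 idx = list(calibration = calib, test = test,
                            spare = spare)),
            class = "bp_personalization_partition")
}
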