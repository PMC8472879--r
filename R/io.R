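#' Record stores, waveform-format ingestion, run configuration
#'
#' Records are stored as a directory with a CSV manifest plus one CSV signal
#' file per subject: plain-text, diffable, and streamable one subject at a
#' time. A minimal PhysioNet waveform-format (format 16) adapter can ingest
#' real PLETH/ABP records; it is an optional convenience and nothing in the
#' pipeline depends on it.
#'
#' @name ppgbp-io
NULL

#' Write a record collection to a directory store
#'
#' @param records List of [wave_record()]s.
#' @param path Store directory (created if missing).
#' @param profiles Optional list of [subject_profile()]s to persist
#'   alongside the signals.
#' @return The store path, invisibly.
#' @export
write_record_store <- function(records, path, profiles = NULL) {
  dir.create(file.path(path, "signals"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r, "bp_wave_record"))
    file <- file.path("signals", paste0(r$subject_id, ".csv"))
    dt <- data.table::data.table(ppg = r$ppg)
    if (!is.null(r$abp)) dt$abp <- r$abp
    data.table::fwrite(dt, file.path(path, file))
    data.frame(subject_id = r$subject_id, fs = r$fs,
               n_samples = length(r$ppg),
               duration_s = length(r$ppg) / r$fs,
               has_abp = !is.null(r$abp), file = file,
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), file.path(path, "manifest.csv"))
  if (!is.null(profiles)) {
    pr <- do.call(rbind, lapply(profiles, function(p) data.frame(
      subject_id = p$subject_id, base_hr = p$base_hr,
      hr_jitter_sd = p$hr_jitter_sd, base_sbp = p$base_sbp,
      base_dbp = p$base_dbp, bp_drift_amplitude = p$bp_drift_amplitude,
      bp_drift_period = p$bp_drift_period,
      offset_1 = p$morphology_offset[1], offset_2 = p$morphology_offset[2],
      offset_3 = p$morphology_offset[3], offset_4 = p$morphology_offset[4],
      noise_sd = p$noise_sd, record_duration = p$record_duration,
      seed = p$seed, stringsAsFactors = FALSE)))
    data.table::fwrite(pr, file.path(path, "profiles.csv"))
  }
  invisible(path)
}

#' Subjects available in a record store
#'
#' @param path Store directory.
#' @return Character vector of subject ids, in manifest order.
#' @export
store_subjects <- function(path) {
  mf <- file.path(path, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in store: ", path)
  as.character(data.table::fread(mf)$subject_id)
}

#' Read one subject's record from a store
#'
#' @param path Store directory.
#' @param subject_id Subject to read.
#' @return A [wave_record()].
#' @export
read_record <- function(path, subject_id) {
  mf <- data.table::fread(file.path(path, "manifest.csv"))
  row <- mf[mf$subject_id == subject_id, ]
  if (!nrow(row)) stop(sprintf("subject '%s' not in manifest", subject_id))
  f <- file.path(path, row$file[1])
  if (!file.exists(f)) {
    stop(sprintf("store is inconsistent: subject '%s' is listed in the manifest but its signal file '%s' is missing",
                 subject_id, row$file[1]))
  }
  dt <- data.table::fread(f)
  wave_record(subject_id, dt$ppg,
              if ("abp" %in% names(dt)) dt$abp else NULL,
              fs = row$fs[1])
}

#' Read a whole record store
#'
#' Subjects are visited sequentially in manifest order, one file at a time,
#' so arbitrarily large stores can be traversed with bounded memory (use
#' [store_subjects()] + [read_record()] for explicit streaming).
#'
#' @param path Store directory.
#' @param subjects Optional subset of subject ids.
#' @return Named list of [wave_record()]s.
#' @export
read_record_store <- function(path, subjects = NULL) {
  ids <- store_subjects(path)
  if (!is.null(subjects)) ids <- ids[ids %in% subjects]
  stats::setNames(lapply(ids, function(s) read_record(path, s)), ids)
}

# --- PhysioNet waveform-format (WFDB) adapter -------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- trimws(readLines(hea_path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  first <- strsplit(lines[1], "\\s+")[[1]]
  name_field <- strsplit(first[1], "/")[[1]]
  nseg <- if (length(name_field) > 1) as.integer(name_field[2]) else 1L
  list(record = name_field[1], n_segments = nseg,
       n_sig = as.integer(first[2]), fs = as.numeric(first[3]),
       n_samples = if (length(first) >= 4) as.numeric(first[4]) else NA,
       body = lines[-1])
}

parse_wfdb_signal_line <- function(line) {
  f <- strsplit(line, "\\s+")[[1]]
  gain_spec <- f[3]
  baseline <- 0
  if (grepl("\\(", gain_spec)) {
    baseline <- as.numeric(sub(".*\\(([-0-9.]+)\\).*", "\\1", gain_spec))
  }
  gain <- as.numeric(sub("^([-0-9.]+).*", "\\1", gain_spec))
  if (!is.finite(gain) || gain == 0) gain <- 200
  list(file = f[1], format = f[2], gain = gain, baseline = baseline,
       description = paste(f[9:length(f)], collapse = " "))
}

read_wfdb_single <- function(hea_path) {
  hd <- parse_wfdb_header(hea_path)
  sigs <- lapply(hd$body[seq_len(hd$n_sig)], parse_wfdb_signal_line)
  fmt <- unique(vapply(sigs, `[[`, "", "format"))
  if (!identical(fmt, "16")) {
    stop("only waveform format 16 is supported, got: ",
         paste(fmt, collapse = ", "))
  }
  dat <- file.path(dirname(hea_path), sigs[[1]]$file)
  raw <- readBin(dat, "integer", n = hd$n_sig * hd$n_samples, size = 2,
                 endian = "little", signed = TRUE)
  m <- matrix(raw, nrow = hd$n_sig)
  out <- lapply(seq_along(sigs), function(i) {
    (m[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
  })
  names(out) <- vapply(sigs, `[[`, "", "description")
  list(signals = out, fs = hd$fs, record = hd$record)
}

#' Ingest PhysioNet waveform-format records
#'
#' Reads format-16 records (single- or multi-segment), extracts the PLETH
#' and ABP channels and returns them as [wave_record()]s; records lacking
#' either channel are skipped with a warning. Multi-segment records are
#' concatenated in header order with the segment boundary sample indices
#' attached as an attribute.
#'
#' @param hea_paths Character vector of `.hea` header file paths.
#' @return Named list of [wave_record()]s (possibly shorter than the input
#'   if records were skipped).
#' @export
wfdb_adapter <- function(hea_paths) {
  out <- list()
  for (hp in hea_paths) {
    hd <- parse_wfdb_header(hp)
    parts <- if (hd$n_segments > 1) {
      seg_lines <- hd$body[seq_len(hd$n_segments)]
      lapply(seg_lines, function(sl) {
        seg_name <- strsplit(sl, "\\s+")[[1]][1]
        read_wfdb_single(file.path(dirname(hp), paste0(seg_name, ".hea")))
      })
    } else list(read_wfdb_single(hp))
    have <- Reduce(intersect, lapply(parts, function(p) names(p$signals)))
    if (!all(c("PLETH", "ABP") %in% have)) {
      warning(sprintf("record '%s' lacks PLETH and/or ABP; skipped",
                      hd$record))
      next
    }
    ppg <- unlist(lapply(parts, function(p) p$signals$PLETH))
    abp <- unlist(lapply(parts, function(p) p$signals$ABP))
    rec <- wave_record(hd$record, ppg, abp, fs = parts[[1]]$fs)
    lens <- vapply(parts, function(p) length(p$signals$PLETH), 0)
    attr(rec, "segment_boundaries") <- cumsum(lens)
    out[[hd$record]] <- rec
  }
  out
}

#' Write a record in waveform format 16 (fixture/testing helper)
#'
#' @param record A [wave_record()] with ABP present.
#' @param dir Output directory.
#' @param name Record name (default: the subject id).
#' @param gain ADC gain (counts per physical unit).
#' @return Path of the header file, invisibly.
#' @export
write_wfdb_record <- function(record, dir, name = record$subject_id,
                              gain = 100) {
  stopifnot(inherits(record, "bp_wave_record"), !is.null(record$abp))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(record$ppg)
  adc <- rbind(round(record$ppg * gain), round(record$abp * gain))
  storage.mode(adc) <- "integer"
  dat <- paste0(name, ".dat")
  writeBin(as.integer(adc), file.path(dir, dat), size = 2,
           endian = "little")
  hea <- c(sprintf("%s 2 %g %d", name, record$fs, n),
           sprintf("%s 16 %g(0)/NU 16 0 0 0 0 PLETH", dat, gain),
           sprintf("%s 16 %g(0)/mmHg 16 0 0 0 0 ABP", dat, gain))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  invisible(file.path(dir, paste0(name, ".hea")))
}

# --- run configuration ------------------------------------------------------

#' Default pipeline configuration
#'
#' Defaults mirror the package's standard analysis settings: 7-beat windows,
#' a -7 dB SNR gate, inclusive plausibility ranges 75-165 / 40-80 mmHg and
#' 50-140 beats/min, a 2000-sample subject cap, Adam with learning rate
#' 0.001 and patience 10, and 10 mmHg evaluation bins.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    cohort = list(n_subjects = 10, seed = 1,
                  fraction_reject_material = 0),
    windowing = list(strategy = "const_beats", length_parameter = 7,
                     overlap = 0),
    snr_threshold = -7,
    plausibility = list(sbp_range = c(75, 165), dbp_range = c(40, 80),
                        hr_range = c(50, 140)),
    split = list(mode = "non_mixed", cap = 2000,
                 subject_fractions = c(0.6, 0.2, 0.2)),
    model = list(architecture = "alexnet1d",
                 hyperparams = list(width = 0.125, dense = c(512))),
    training = list(learning_rate = 0.001, max_epochs = 200, patience = 10,
                    batch_size = 128, monitor = "val_mae"),
    evaluation = list(bin_width = 10),
    seed = 1
  )
}

#' Validate a pipeline configuration
#'
#' @param cfg Nested configuration list (see [default_run_config()]).
#' @return The validated config, invisibly; aborts with an error naming the
#'   offending field otherwise.
#' @export
validate_run_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid config field `%s`: %s", field, why),
         call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$cohort$n_subjects) || cfg$cohort$n_subjects < 2) {
    fail("cohort.n_subjects", "must be a number >= 2")
  }
  if (!num1(cfg$seed)) fail("seed", "must be a single number")
  if (!cfg$windowing$strategy %in% c("const_time", "const_beats")) {
    fail("windowing.strategy", "must be 'const_time' or 'const_beats'")
  }
  if (!num1(cfg$windowing$length_parameter) ||
      cfg$windowing$length_parameter <= 0) {
    fail("windowing.length_parameter", "must be a positive number")
  }
  if (!num1(cfg$snr_threshold)) {
    fail("snr_threshold", "must be a single number (dB)")
  }
  for (rng in c("sbp_range", "dbp_range", "hr_range")) {
    r <- cfg$plausibility[[rng]]
    if (!is.numeric(r) || length(r) != 2 || r[1] >= r[2]) {
      fail(paste0("plausibility.", rng), "must be a numeric (low, high) pair")
    }
  }
  if (!cfg$split$mode %in% c("non_mixed", "mixed")) {
    fail("split.mode", "must be 'non_mixed' or 'mixed'")
  }
  if (!num1(cfg$split$cap) || cfg$split$cap <= 0) {
    fail("split.cap", "must be a positive number")
  }
  if (!cfg$model$architecture %in% c("alexnet1d", "resnet1d",
                                     "spectrotemporal", "cnn_lstm",
                                     "mean_regressor")) {
    fail("model.architecture", "unknown architecture")
  }
  if (!num1(cfg$training$learning_rate) || cfg$training$learning_rate <= 0) {
    fail("training.learning_rate", "must be a positive number")
  }
  if (!num1(cfg$evaluation$bin_width) || cfg$evaluation$bin_width <= 0) {
    fail("evaluation.bin_width", "must be a positive number")
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg Configuration list.
#' @return `read_run_config` returns the validated config.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
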