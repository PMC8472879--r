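#' Synthetic PPG/ABP cohorts
#'
#' The synthetic generator produces paired PPG and arterial blood pressure
#' (ABP) waveforms per subject, plus camera-style RGB traces for the remote
#' PPG workflow. Each subject has a fixed, subject-specific offset applied to
#' the population mapping from (SBP, DBP, HR) to pulse morphology; this
#' offset is what makes train/test subject leakage measurable downstream.
#'
#' @name ppgbp-synthetic
NULL

# ---------------------------------------------------------------------------
# Pulse templates

# Smooth two-bump PPG pulse over phase in [0, 1): an asymmetric systolic
# peak plus a Gaussian dicrotic bump. All parameters dimensionless.
ppg_pulse_template <- function(phase, sys_width, dicrotic_amp, dicrotic_delay,
                               asym) {
  mu1 <- 0.23
  wl <- sys_width * (1 - asym)
  wr <- sys_width * (1 + asym)
  w <- ifelse(phase < mu1, wl, wr)
  bump1 <- exp(-0.5 * ((phase - mu1) / w)^2)
  bump2 <- dicrotic_amp * exp(-0.5 * ((phase - dicrotic_delay) / 0.07)^2)
  bump1 + bump2
}

# Fixed ABP pulse shape (rescaled per beat so each beat spans [DBP, SBP]).
abp_pulse_template <- function(phase) {
  exp(-0.5 * ((phase - 0.30) / 0.12)^2) +
    0.25 * exp(-0.5 * ((phase - 0.62) / 0.08)^2)
}

# Population morphology <- (SBP, DBP, HR) mapping: linear in standardized
# BP/HR, plus the additive subject-specific offset vector, clamped to
# physically sensible template ranges. Vectorized over beats.
morphology_from_bp <- function(sbp, dbp, hr, offset) {
  s <- (sbp - 120) / 30
  d <- (dbp - 70) / 20
  h <- (hr - 75) / 30
  list(
    sys_width      = clamp(0.11 - 0.020 * s + 0.010 * d + offset[1], 0.05, 0.20),
    dicrotic_amp   = clamp(0.35 - 0.12 * s - 0.05 * h + offset[2], 0.02, 0.65),
    dicrotic_delay = clamp(0.55 + 0.05 * s + 0.03 * d + offset[3], 0.42, 0.78),
    asym           = clamp(0.25 + 0.10 * d - 0.05 * h + offset[4], 0.00, 0.60)
  )
}

# ---------------------------------------------------------------------------
# Profiles and records

#' Create a synthetic subject profile
#'
#' @param subject_id Character identifier.
#' @param base_hr Mean heart rate in beats/min.
#' @param hr_jitter_sd Beat-to-beat heart-rate jitter standard deviation
#'   (beats/min, AR(1) across beats).
#' @param base_sbp,base_dbp Baseline systolic/diastolic pressure in mmHg;
#'   `base_sbp` must exceed `base_dbp` by at least 20 mmHg unless
#'   `allow_implausible = TRUE`.
#' @param bp_drift_amplitude Amplitude (mmHg) of the slow sinusoidal SBP
#'   drift; DBP drifts with half that amplitude, in phase. Beat-level AR(1)
#'   pressure jitter scales with this amplitude and vanishes with it.
#' @param bp_drift_period Drift period in seconds.
#' @param morphology_offset Numeric length-4 subject-specific offset added to
#'   the population morphology mapping (systolic width, dicrotic amplitude,
#'   dicrotic delay, asymmetry). Fixed for the life of the subject.
#' @param noise_sd Additive white-noise standard deviation on the PPG, in
#'   signal units (the noise-free pulse has unit peak amplitude).
#' @param record_duration Record length in seconds (>= 10).
#' @param seed Integer seed controlling all randomness for this subject.
#' @param allow_implausible Allow heart rates / pressures outside the usual
#'   plausible ranges (used to engineer filter-rejected material).
#' @return An object of class `bp_subject_profile`.
#' @export
subject_profile <- function(subject_id, base_hr = 75, hr_jitter_sd = 1.5,
                            base_sbp = 120, base_dbp = 70,
                            bp_drift_amplitude = 5, bp_drift_period = 180,
                            morphology_offset = c(0, 0, 0, 0),
                            noise_sd = 0.02, record_duration = 300,
                            seed = 1L, allow_implausible = FALSE) {
  stopifnot_scalar_pos(record_duration, "record_duration")
  if (record_duration < 10) stop("`record_duration` must be at least 10 s")
  if (base_dbp >= base_sbp) stop("`base_dbp` must be below `base_sbp`")
  if (!allow_implausible) {
    if (base_sbp - base_dbp < 20) {
      stop("`base_sbp` must exceed `base_dbp` by at least 20 mmHg")
    }
    if (base_hr < 50 || base_hr > 140) {
      stop("`base_hr` must lie in [50, 140] beats/min")
    }
  }
  if (length(morphology_offset) != 4L) {
    stop("`morphology_offset` must have length 4")
  }
  structure(list(
    subject_id = as.character(subject_id), base_hr = base_hr,
    hr_jitter_sd = hr_jitter_sd, base_sbp = base_sbp, base_dbp = base_dbp,
    bp_drift_amplitude = bp_drift_amplitude,
    bp_drift_period = bp_drift_period,
    morphology_offset = as.numeric(morphology_offset),
    noise_sd = noise_sd, record_duration = record_duration,
    seed = as.integer(seed)
  ), class = "bp_subject_profile")
}

#' Construct a waveform record
#'
#' A `bp_wave_record` couples a PPG series with an optional ABP series at a
#' common sampling rate.
#'
#' @param subject_id Character identifier.
#' @param ppg Numeric PPG series (signal units).
#' @param abp Numeric ABP series (mmHg) of the same length, or `NULL`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `bp_wave_record`.
#' @export
wave_record <- function(subject_id, ppg, abp = NULL, fs = 125) {
  stopifnot_scalar_pos(fs, "fs")
  if (!is.null(abp) && length(abp) != length(ppg)) {
    stop("`ppg` and `abp` must have equal length")
  }
  structure(list(subject_id = as.character(subject_id),
                 ppg = as.numeric(ppg),
                 abp = if (is.null(abp)) NULL else as.numeric(abp),
                 fs = fs),
            class = "bp_wave_record")
}

#' @export
print.bp_wave_record <- function(x, ...) {
  cat(sprintf("<bp_wave_record> subject %s: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, length(x$ppg), x$fs, length(x$ppg) / x$fs,
              if (is.null(x$abp)) ", no ABP" else ", paired ABP"))
  invisible(x)
}

# Beat-by-beat schedule: start times (s), periods (s), instantaneous HR and
# per-beat SBP/DBP along the slow drift trajectory. Uses the current RNG.
beat_schedule <- function(profile) {
  dur <- profile$record_duration
  phase0 <- stats::runif(1, 0, 2 * pi)
  rho <- 0.8
  starts <- numeric(0); hrs <- numeric(0)
  t0 <- 0; j <- 0
  repeat {
    j <- rho * j + sqrt(1 - rho^2) * stats::rnorm(1, sd = profile$hr_jitter_sd)
    hr <- clamp(profile$base_hr + j, 25, 220)
    starts <- c(starts, t0); hrs <- c(hrs, hr)
    t0 <- t0 + 60 / hr
    if (t0 >= dur) break
  }
  k <- length(starts)
  drift <- profile$bp_drift_amplitude *
    sin(2 * pi * starts / profile$bp_drift_period + phase0)
  # beat-level pressure jitter scales with the drift amplitude so that
  # drift-free profiles have strictly constant per-beat pressures
  jit <- numeric(k); e <- 0
  for (i in seq_len(k)) {
    e <- 0.7 * e + sqrt(1 - 0.7^2) *
      stats::rnorm(1, sd = 0.1 * profile$bp_drift_amplitude)
    jit[i] <- e
  }
  list(start = starts, period = 60 / hrs, hr = hrs,
       sbp = profile$base_sbp + drift + jit,
       dbp = profile$base_dbp + 0.5 * drift + 0.5 * jit,
       drift_phase = phase0)
}

#' Generate one subject's paired PPG/ABP record
#'
#' The ABP oscillates beat-synchronously between the instantaneous diastolic
#' and systolic trajectories; within each complete beat the sampled waveform
#' attains the beat's SBP and DBP exactly. The PPG beat shape is the
#' population morphology function of the instantaneous (SBP, DBP, HR) plus
#' the subject's fixed morphology offset, with additive white noise.
#'
#' @param profile A [subject_profile()].
#' @param fs Sampling rate in Hz (default 125).
#' @param seed Seed; defaults to the profile's own seed.
#' @return A [wave_record()] with `profile` attached as an attribute.
#' @export
generate_subject_record <- function(profile, fs = 125, seed = profile$seed) {
  stopifnot(inherits(profile, "bp_subject_profile"))
  stopifnot_scalar_pos(fs, "fs")
  if (fs <= 2 * (profile$base_hr / 60 * 4)) {
    stop("`fs` too low for the pulse fundamental and its harmonics")
  }
  with_seed(seed, {
    n <- round(profile$record_duration * fs)
    t <- (0:(n - 1)) / fs
    bs <- beat_schedule(profile)
    k_of_t <- findInterval(t, bs$start)
    phase <- (t - bs$start[k_of_t]) / bs$period[k_of_t]
    nbeats <- length(bs$start)

    # ABP: fixed pulse shape, rescaled per beat so the sampled waveform of
    # every complete beat spans [dbp_k, sbp_k] exactly.
    shape <- abp_pulse_template(phase)
    abp <- numeric(n)
    full_grid <- abp_pulse_template(seq(0, 1, length.out = 512))
    g_lo <- min(full_grid); g_hi <- max(full_grid)
    for (k in seq_len(nbeats)) {
      idx <- which(k_of_t == k)
      if (!length(idx)) next
      complete <- (k < nbeats) ||
        (bs$start[k] + bs$period[k] <= profile$record_duration + 1e-9)
      if (complete && length(idx) >= 4) {
        lo <- min(shape[idx]); hi <- max(shape[idx])
      } else {
        lo <- g_lo; hi <- g_hi
      }
      abp[idx] <- bs$dbp[k] + (bs$sbp[k] - bs$dbp[k]) *
        (shape[idx] - lo) / (hi - lo)
    }

    # PPG: per-beat morphology from the population mapping + subject offset.
    mp <- morphology_from_bp(bs$sbp, bs$dbp, bs$hr, profile$morphology_offset)
    ppg <- ppg_pulse_template(phase,
                              sys_width = mp$sys_width[k_of_t],
                              dicrotic_amp = mp$dicrotic_amp[k_of_t],
                              dicrotic_delay = mp$dicrotic_delay[k_of_t],
                              asym = mp$asym[k_of_t])
    if (profile$noise_sd > 0) {
      ppg <- ppg + stats::rnorm(n, sd = profile$noise_sd)
    }
    rec <- wave_record(profile$subject_id, ppg, abp, fs)
    attr(rec, "profile") <- profile
    attr(rec, "drift_phase") <- bs$drift_phase
    rec
  })
}

# ---------------------------------------------------------------------------
# Cohorts

#' Cohort generation settings
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; fully determines the cohort.
#' @param fraction_reject_material Fraction of subjects engineered to violate
#'   the systolic plausibility range (their baseline SBP is placed above
#'   165 mmHg so every window is later rejected).
#' @param subject_size_distribution Log-normal parameters for the per-subject
#'   record duration in seconds (`meanlog`, `sdlog`, plus clamping bounds
#'   `min_s`, `max_s`). Long-tailed by construction: a cohort spans records
#'   from a couple of minutes to hours.
#' @param population Population-level parameter ranges (means/sds and
#'   clamping ranges for baseline SBP/DBP/HR, drift amplitude and period,
#'   PPG noise, and the standard deviations of the four morphology-offset
#'   components).
#' @return An object of class `bp_cohort_config`.
#' @export
cohort_config <- function(n_subjects, seed = 1L,
                          fraction_reject_material = 0,
                          subject_size_distribution = list(
                            meanlog = log(300), sdlog = 0.6,
                            min_s = 60, max_s = 7200),
                          population = list()) {
  if (n_subjects < 2) stop("`n_subjects` must be at least 2")
  if (fraction_reject_material < 0 || fraction_reject_material > 1) {
    stop("`fraction_reject_material` must lie in [0, 1]")
  }
  pop <- utils::modifyList(list(
    sbp_mean = 125, sbp_sd = 15, sbp_range = c(88, 162),
    dbp_mean = 64, dbp_sd = 7, dbp_range = c(44, 78),
    min_gap = 25,
    hr_mean = 78, hr_sd = 12, hr_range = c(55, 115),
    hr_jitter_sd = 1.5,
    drift_amplitude_range = c(2, 8), drift_period_range = c(90, 420),
    noise_sd = 0.02,
    offset_sd = c(0.012, 0.08, 0.030, 0.060)
  ), population)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 fraction_reject_material = fraction_reject_material,
                 subject_size_distribution = subject_size_distribution,
                 population = pop),
            class = "bp_cohort_config")
}

#' Generate a synthetic cohort of paired PPG/ABP records
#'
#' Subject baselines are drawn from the configured population, record
#' durations from a long-tailed log-normal, and each subject receives a fixed
#' morphology-offset vector. Reject-material subjects get baseline SBP above
#' the plausible range. The result is fully determined by the config seed.
#'
#' @param config A [cohort_config()].
#' @param fs Sampling rate in Hz.
#' @return A list of class `bp_cohort` with elements `records`, `profiles`
#'   and `config`.
#' @export
generate_cohort <- function(config, fs = 125) {
  stopifnot(inherits(config, "bp_cohort_config"))
  pop <- config$population
  sz <- config$subject_size_distribution
  n_reject <- ceiling(config$fraction_reject_material * config$n_subjects)
  profiles <- with_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(i) {
      id <- sprintf("S%04d", i)
      sbp <- clamp(stats::rnorm(1, pop$sbp_mean, pop$sbp_sd),
                   pop$sbp_range[1], pop$sbp_range[2])
      dbp <- clamp(stats::rnorm(1, pop$dbp_mean, pop$dbp_sd),
                   pop$dbp_range[1], pop$dbp_range[2])
      dbp <- min(dbp, sbp - pop$min_gap)
      reject <- i <= n_reject
      if (reject) sbp <- stats::runif(1, 170, 185)
      hr <- clamp(stats::rnorm(1, pop$hr_mean, pop$hr_sd),
                  pop$hr_range[1], pop$hr_range[2])
      dur_raw <- stats::rlnorm(1, sz$meanlog, sz$sdlog)
      dur <- clamp(dur_raw, sz$min_s, sz$max_s)
      pr <- subject_profile(
        subject_id = id, base_hr = hr, hr_jitter_sd = pop$hr_jitter_sd,
        base_sbp = sbp, base_dbp = dbp,
        bp_drift_amplitude = stats::runif(1, pop$drift_amplitude_range[1],
                                          pop$drift_amplitude_range[2]),
        bp_drift_period = stats::runif(1, pop$drift_period_range[1],
                                       pop$drift_period_range[2]),
        morphology_offset = stats::rnorm(4, 0, pop$offset_sd),
        noise_sd = pop$noise_sd, record_duration = dur,
        seed = derive_seed(config$seed, id),
        allow_implausible = TRUE
      )
      pr$engineered_reject <- reject
      pr$duration_raw <- dur_raw
      pr
    })
  })
  records <- lapply(profiles, generate_subject_record, fs = fs)
  names(records) <- vapply(profiles, `[[`, "", "subject_id")
  names(profiles) <- names(records)
  structure(list(records = records, profiles = profiles, config = config),
            class = "bp_cohort")
}

#' @export
print.bp_cohort <- function(x, ...) {
  durs <- vapply(x$records, function(r) length(r$ppg) / r$fs, 0)
  cat(sprintf("<bp_cohort> %d subjects, durations %.0f-%.0f s (seed %d)\n",
              length(x$records), min(durs), max(durs), x$config$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# rPPG traces

#' Generate a camera-style RGB trace with embedded pulse
#'
#' Emulates the per-frame ROI-mean RGB triplet of a face video: a slowly
#' varying common-mode baseline intensity, channel-specific pulse modulation
#' at the instantaneous heart rate (strongest in green), optional
#' motion-artifact transients, and sensor noise. Reference blood pressure is
#' emitted on an inclusive one-minute grid, read off the drift trajectory at
#' each minute mark (no averaging), as a bedside monitor would report it.
#'
#' @param profile A [subject_profile()]. Its `noise_sd` is reused as the
#'   absolute intensity noise; its drift parameters drive the reference BP.
#' @param fs Frame rate in Hz (default 32).
#' @param pulse_strength Relative pulse modulation depth in (0, 1].
#'   Zero disables the embedded pulse entirely.
#' @param artifact_rate Motion artifact events per minute.
#' @param seed Seed; defaults to the profile seed.
#' @param channel_weights Relative pulse-modulation strengths for (R, G, B).
#' @param pulse_template Either `"ppg"` (the subject's PPG morphology) or
#'   `"rppg"` (a rounder, phase-shifted waveform emulating the domain shift
#'   between contact PPG and camera-derived pulses).
#' @return A list of class `bp_rppg_trace` with the RGB matrix, frame rate,
#'   minute-grid reference BP, and the hidden embedded pulse (for testing).
#' @export
generate_rppg_trace <- function(profile, fs = 32, pulse_strength = 0.05,
                                artifact_rate = 0, seed = profile$seed,
                                channel_weights = c(0.33, 0.77, 0.53),
                                pulse_template = c("ppg", "rppg")) {
  stopifnot(inherits(profile, "bp_subject_profile"))
  if (fs <= 0) stop("`fs` must be positive")
  if (pulse_strength < 0 || pulse_strength > 1) {
    stop("`pulse_strength` must lie in [0, 1]")
  }
  pulse_template <- match.arg(pulse_template)
  with_seed(seed, {
    dur <- profile$record_duration
    n <- round(dur * fs)
    t <- (0:(n - 1)) / fs
    bs <- beat_schedule(profile)
    k_of_t <- findInterval(t, bs$start)
    phase <- (t - bs$start[k_of_t]) / bs$period[k_of_t]
    if (pulse_strength > 0) {
      mp <- morphology_from_bp(bs$sbp, bs$dbp, bs$hr,
                               profile$morphology_offset)
      if (pulse_template == "ppg") {
        pulse <- ppg_pulse_template(phase,
                                    sys_width = mp$sys_width[k_of_t],
                                    dicrotic_amp = mp$dicrotic_amp[k_of_t],
                                    dicrotic_delay = mp$dicrotic_delay[k_of_t],
                                    asym = mp$asym[k_of_t])
      } else {
        # camera-style rendering of the same BP-dependent morphology:
        # broader systolic peak, attenuated and delayed dicrotic bump, plus
        # a rounded baseline component. The pulse still encodes blood
        # pressure (otherwise transfer learning would have nothing to
        # recover) but its waveform family differs from the contact PPG -
        # the domain shift the transfer protocol is meant to bridge.
        pulse <- ppg_pulse_template(
          phase,
          sys_width = clamp(1.5 * mp$sys_width[k_of_t], 0.05, 0.30),
          dicrotic_amp = 0.4 * mp$dicrotic_amp[k_of_t],
          dicrotic_delay = clamp(mp$dicrotic_delay[k_of_t] + 0.04,
                                 0.42, 0.82),
          asym = 0.6 * mp$asym[k_of_t]) +
          0.25 * (-cos(2 * pi * phase))
      }
      pulse <- pulse - mean(pulse)
      if (stats::sd(pulse) > 0) pulse <- pulse / stats::sd(pulse)
    } else {
      pulse <- numeric(n)
    }

    base_levels <- c(0.55, 0.45, 0.40)
    wander <- 0.01 * sin(2 * pi * t / 45 + stats::runif(1, 0, 2 * pi))
    rgb <- matrix(0, n, 3, dimnames = list(NULL, c("r", "g", "b")))
    for (c3 in 1:3) {
      rgb[, c3] <- base_levels[c3] * (1 + wander) *
        (1 + pulse_strength * channel_weights[c3] * pulse)
    }
    if (artifact_rate > 0) {
      n_art <- stats::rpois(1, artifact_rate * dur / 60)
      if (n_art > 0) {
        times <- stats::runif(n_art, 0, dur)
        for (a in seq_len(n_art)) {
          amp <- stats::runif(1, 0.05, 0.2) * sample(c(-1, 1), 1)
          dt <- t - times[a]
          tr <- ifelse(dt >= 0, amp * exp(-dt / 0.5), 0)
          for (c3 in 1:3) {
            rgb[, c3] <- rgb[, c3] + tr * stats::runif(1, 0.8, 1.2)
          }
        }
      }
    }
    if (profile$noise_sd > 0) {
      rgb <- rgb + matrix(stats::rnorm(3 * n, sd = profile$noise_sd), n, 3)
    }

    minute_grid <- seq(0, dur, by = 60)
    ref_drift <- profile$bp_drift_amplitude *
      sin(2 * pi * minute_grid / profile$bp_drift_period + bs$drift_phase)
    reference <- data.frame(
      time_s = minute_grid,
      sbp = profile$base_sbp + ref_drift,
      dbp = profile$base_dbp + 0.5 * ref_drift
    )
    structure(list(rgb = rgb, fs = fs, reference = reference,
                   hidden_pulse = pulse, profile = profile),
              class = "bp_rppg_trace")
  })
}
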