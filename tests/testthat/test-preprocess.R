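test_that("the band-pass filter removes DC and passes the pulse band", {
  fs <- 125
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  mk <- function(x) wave_record("F", x, fs = fs)
  mid <- function(x) x[(5 * fs):(15 * fs)]   # away from edge transients

  dc <- bandpass_ppg(mk(rep(2, length(t))))
  expect_lt(max(abs(mid(dc$ppg))), 0.01)

  s2 <- bandpass_ppg(mk(sin(2 * pi * 2 * t)))
  expect_lt(abs(max(mid(s2$ppg)) - 1), 0.05)

  # analytic attenuation of the designed zero-phase filter at 0.1 Hz
  slow <- bandpass_ppg(mk(sin(2 * pi * 0.1 * t)))
  h2 <- ppgbp:::bandpass_response(0.1, fs)
  expect_lt(sqrt(h2), 0.04)                       # designed stop-band gain
  expect_lt(max(abs(mid(slow$ppg))), 0.2)
  expect_lt(max(abs(mid(slow$ppg))), sqrt(h2) + 1e-3)  # gain + transient

  expect_error(bandpass_ppg(mk(t), low = 0, high = 8), "cut-offs")
  expect_error(bandpass_ppg(mk(t), low = 1, high = 70), "cut-offs")
  # ABP stays untouched
  r <- wave_record("G", sin(2 * pi * t), abp = 100 + sin(t), fs = fs)
  expect_identical(bandpass_ppg(r)$abp, r$abp)
})

test_that("heart rate is the dominant spectral component in band", {
  fs <- 125
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  expect_equal(estimate_heart_rate(sin(2 * pi * 1.5 * t), fs), 90,
               tolerance = 0.02)
  two <- 2 * sin(2 * pi * 1 * t) + sin(2 * pi * 2 * t)
  expect_equal(estimate_heart_rate(two, fs), 60, tolerance = 0.02)
  expect_error(estimate_heart_rate(numeric(100) , fs), "all-zero")

  set.seed(1)
  p <- quiet_profile("H", base_hr = 72, record_duration = 40, seed = 2)
  r <- generate_subject_record(p)
  noisy <- r$ppg + rnorm(length(r$ppg), sd = 0.1)
  bin_bpm <- 60 * fs / 2^ceiling(log2(fs / 0.02))
  expect_lt(abs(estimate_heart_rate(noisy, fs) - 72), 2 * bin_bpm + 1e-9)
})

test_that("const_time cropping yields disjoint fixed-duration windows", {
  p <- quiet_profile("W", base_hr = 60, record_duration = 70, seed = 1)
  r <- generate_subject_record(p)
  ws <- crop_windows(r, windowing_config("const_time", 7))
  expect_equal(nrow(ws$x), 10)
  expect_equal(ncol(ws$x), 875)
  expect_equal(diff(ws$meta$source_offset), rep(875, 9))
  # too-short record: empty window set, not an error
  short <- wave_record("S", rnorm(100), fs = 125)
  expect_equal(ppgbp:::n_windows(crop_windows(short,
                                              windowing_config("const_time", 7))), 0)
})

test_that("const_beats windows span the estimated beats and resample to N_P x 125", {
  p <- quiet_profile("W2", base_hr = 84, record_duration = 80, seed = 5)
  r <- generate_subject_record(p)
  ws <- crop_windows(r, windowing_config("const_beats", 7))
  expect_true(all(ncol(ws$x) == 875))
  # span = 7 * (60/84) s = 5 s = 625 samples, up to HR-estimate resolution
  expect_true(all(abs(ws$meta$span - 625) <= 7))
  # at exactly 60 bpm the resampling is the identity up to interpolation
  p60 <- quiet_profile("W3", base_hr = 60, record_duration = 40, seed = 6)
  r60 <- generate_subject_record(p60)
  ws60 <- crop_windows(r60, windowing_config("const_beats", 7))
  raw <- r60$ppg[ws60$meta$source_offset[2] + 0:(ws60$meta$span[2] - 1)]
  if (length(raw) == 875) {
    expect_equal(as.numeric(ws60$x[2, ]), raw, tolerance = 1e-6)
  }
  expect_true(all(abs(ws60$meta$span - 875) <= 12))
})

test_that("Fourier resampling hits the target length and preserves tones", {
  x <- sin(2 * pi * 7 * seq(0, 1, length.out = 626)[-626])  # 7 cycles, 625 samples
  y <- resample_to_effective_60bpm(x, 7, 125)
  expect_length(y, 875)
  # dominant bin of the output at 1 Hz under the nominal 125 Hz rate
  sp <- abs(fft(y - mean(y)))[2:438]
  expect_equal(which.max(sp) * 125 / 875, 1, tolerance = 1e-9)
  # identity case
  z <- rnorm(875)
  expect_identical(resample_to_effective_60bpm(z, 7, 125), z)
  expect_error(resample_to_effective_60bpm(numeric(0), 7), "nonempty")
  expect_error(resample_to_effective_60bpm(z, 0), "at least 1")
})

test_that("derivative channels follow the central-difference operator", {
  fs <- 125
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  ramp <- discrete_derivative(3 * t, fs)
  expect_equal(ramp[2:(length(t) - 1)], rep(3, length(t) - 2),
               tolerance = 1e-9)
  d2 <- discrete_derivative(ramp, fs)
  expect_lt(max(abs(d2[3:(length(t) - 2)])), 1e-9)

  s <- sin(2 * pi * t)
  ds <- discrete_derivative(s, fs)
  expect_equal(ds[5:245], 2 * pi * cos(2 * pi * t)[5:245], tolerance = 1e-3)

  set.seed(3)
  ws <- ppgbp:::new_window_set(matrix(rnorm(875), 1), data.frame(
    subject_id = "d", source_offset = 1L, span = 875L, estimated_hr = 60,
    snr_db = NA_real_, strategy = "const_time"), list(NULL), fs, fs,
    windowing_config("const_time", 7))
  w3 <- add_derivative_channels(ws)
  expect_equal(dim(w3$x), c(1, 875, 3))
  # d2 is exactly the derivative operator applied twice
  expect_identical(as.numeric(w3$x[1, , 3]),
                   discrete_derivative(discrete_derivative(w3$x[1, , 1], fs), fs))
  expect_error(add_derivative_channels(w3), "already")
})

test_that("SNR follows the band-energy definition", {
  expect_equal(snr_from_energies(10, 1), 10)
  expect_equal(snr_from_energies(5, 5), 0)
  expect_identical(snr_from_energies(3, 0), Inf)

  # constructed two-tone spectrum with a 10:1 in-band energy ratio -> 10 dB;
  # tones on exact DFT bins (integer cycles per 7 s) so no energy leaks
  fs <- 125; n <- 875
  t <- (0:(n - 1)) / fs
  f_pulse <- 9 / 7     # pulse tone inside the heart-rate band
  f_rest <- 4          # far from the pulse bands
  x <- sqrt(10) * sin(2 * pi * f_pulse * t) + 1 * sin(2 * pi * f_rest * t)
  s <- compute_snr(x, fs)
  expect_equal(s$snr_db, 10, tolerance = 1e-6)
  x0 <- sin(2 * pi * f_pulse * t) + sin(2 * pi * f_rest * t)
  expect_equal(compute_snr(x0, fs)$snr_db, 0, tolerance = 1e-6)

  # amplitude invariance
  set.seed(4)
  w <- noisy_pulse_window()
  expect_equal(compute_snr(w, fs)$snr_db, compute_snr(5 * w, fs)$snr_db,
               tolerance = 1e-9)
})

test_that("compute_snr matches the brute-force periodogram oracle", {
  set.seed(7)
  devs <- replicate(300, {
    w <- noisy_pulse_window(f = runif(1, 0.9, 2.4),
                            amp = runif(1, 0.3, 2),
                            noise_sd = runif(1, 0.1, 1))
    abs(compute_snr(w, 125)$snr_db - snr_oracle(w, 125))
  })
  expect_lt(max(devs), 1e-6)
})

test_that("added white noise monotonically lowers the measured SNR", {
  set.seed(8)
  t <- seq(0, 7 - 1 / 125, by = 1 / 125)
  pulse <- sin(2 * pi * 1.2 * t)
  noise <- rnorm(length(t))
  snrs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6),
                 function(s) compute_snr(pulse + s * noise, 125)$snr_db, 0)
  violations <- sum(diff(snrs) >= 0)
  expect_lte(violations, 1)
})

test_that("SNR gating keeps windows at or above the threshold, in order", {
  ws <- ppgbp:::new_window_set(
    matrix(rnorm(3 * 10), 3), data.frame(
      subject_id = "g", source_offset = c(1L, 11L, 21L), span = 10L,
      estimated_hr = 60, snr_db = c(-9, -7, -3), strategy = "const_time"),
    vector("list", 3), 125, 125, windowing_config("const_time", 7))
  kept <- gate_by_snr(ws, -7)
  expect_equal(ppgbp:::n_windows(kept), 2)
  expect_equal(kept$meta$snr_db, c(-7, -3))
  expect_equal(ppgbp:::n_windows(gate_by_snr(ws, -Inf)), 3)
  ws$meta$snr_db[2] <- NA
  expect_error(gate_by_snr(ws), "computed")
})

test_that("normalization gives zero mean and unit population variance", {
  expect_equal(normalize_vector(c(1, 2, 3)),
               c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  set.seed(9)
  x <- rnorm(100, 5, 3)
  z <- normalize_vector(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
  expect_equal(normalize_vector(z), z, tolerance = 1e-9)
  expect_error(normalize_vector(rep(2, 10)), "constant")

  ws <- ppgbp:::new_window_set(
    rbind(rnorm(50), rep(1, 50)), data.frame(
      subject_id = "n", source_offset = c(1L, 51L), span = 50L,
      estimated_hr = 60, snr_db = 0, strategy = "const_time"),
    vector("list", 2), 125, 125, windowing_config("const_time", 7))
  nz <- normalize_windows(ws)
  expect_equal(ppgbp:::n_windows(nz), 1)
  expect_equal(attr(nz, "dropped")$reason, "constant_channel")
  expect_equal(mean(nz$x[1, ]), 0, tolerance = 1e-9)
})

test_that("POS removes common-mode intensity and is scale invariant", {
  n <- 200
  const <- matrix(0.5, n, 3)
  expect_equal(pos_extract(const, 32), numeric(n))
  set.seed(10)
  rgb <- matrix(runif(3 * n, 0.4, 0.6), n, 3)
  expect_equal(pos_extract(3 * rgb, 32), pos_extract(rgb, 32),
               tolerance = 1e-12)
  expect_error(pos_extract(rgb[1:10, ], 32), "shorter")
  rgb0 <- rgb; rgb0[, 2] <- 0
  expect_error(pos_extract(rgb0, 32), "zero running mean")
})

test_that("POS recovers an embedded pulse at realistic modulation depth", {
  p <- quiet_profile("P", base_hr = 66, record_duration = 120, seed = 4)
  tr <- generate_rppg_trace(p, fs = 32, pulse_strength = 0.05)
  pulse <- pos_extract(tr$rgb, 32)
  expect_gte(cor(pulse, tr$hidden_pulse), 0.9)
})

test_that("the pipeline applies filter, window, SNR gate, normalize in order", {
  expect_identical(pipeline_stage_order(),
                   c("bandpass", "window", "snr_gate", "normalize"))
  p <- quiet_profile("PL", base_hr = 66, record_duration = 60, seed = 12)
  r <- generate_subject_record(p)
  ws <- preprocess_record(r, windowing_config("const_beats", 7))
  at <- attr(ws, "attrition")
  expect_identical(names(at), c("cropped", "snr_gated", "normalized"))
  expect_true(all(diff(at) <= 0))   # attrition never adds windows
  # every surviving window is normalized
  mu <- rowMeans(ws$x)
  expect_lt(max(abs(mu)), 1e-9)
})
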