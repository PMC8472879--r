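test_that("drift-free records oscillate exactly between the baseline pressures", {
  p <- quiet_profile("A", base_hr = 60, base_sbp = 120, base_dbp = 60,
                     seed = 7)
  r <- generate_subject_record(p)
  ex <- detect_abp_extrema(r$abp, r$fs, hr_hint = 60)
  expect_gte(nrow(ex$systolic), 25)
  expect_true(all(abs(ex$systolic$value - 120) <= 0.5))
  expect_true(all(abs(ex$diastolic$value - 60) <= 0.5))
  # complete interior beats attain the extremes exactly
  interior <- ex$systolic$value[2:(nrow(ex$systolic) - 1)]
  expect_equal(interior, rep(120, length(interior)))
})

test_that("the PPG spectrum peaks at the pulse rate", {
  p <- quiet_profile("B", base_hr = 72, record_duration = 60, seed = 3)
  r <- generate_subject_record(p)
  # 72 beats/min = 1.2 Hz; spectral estimate within one padded-FFT bin
  hr <- estimate_heart_rate(r$ppg, r$fs)
  bin_bpm <- 60 * r$fs / 2^ceiling(log2(r$fs / 0.02))
  expect_lt(abs(hr - 72), 2 * bin_bpm + 1e-9)
})

test_that("generation is deterministic and rejects invalid profiles", {
  p <- quiet_profile("C", seed = 11)
  r1 <- generate_subject_record(p)
  r2 <- generate_subject_record(p)
  expect_identical(r1$ppg, r2$ppg)
  expect_identical(r1$abp, r2$abp)
  expect_error(subject_profile("X", base_sbp = 100, base_dbp = 110),
               "below")
  expect_error(subject_profile("X", record_duration = 5), "10 s")
  expect_error(generate_subject_record(p, fs = 5), "too low")
})

test_that("the subject offset changes pulse morphology at identical vitals", {
  base <- list(base_hr = 70, base_sbp = 125, base_dbp = 70)
  p1 <- do.call(quiet_profile, c(list("S1", seed = 2), base))
  p2 <- do.call(quiet_profile,
                c(list("S2", seed = 2,
                       morphology_offset = c(0.02, 0.15, 0.05, 0.1)), base))
  r1 <- generate_subject_record(p1)
  r2 <- generate_subject_record(p2)
  d <- mean(abs(r1$ppg - r2$ppg))
  expect_gt(d, 0.005)
  # identical vitals: the ABP trajectories stay the same
  expect_equal(r1$abp, r2$abp, tolerance = 1e-12)
})

test_that("cohorts are seed-deterministic with long-tailed record sizes", {
  cfg <- cohort_config(n_subjects = 5, seed = 1)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$profiles, c2$profiles)

  # empirical duration distribution matches the configured log-normal
  cfg50 <- cohort_config(n_subjects = 50, seed = 4)
  co <- generate_cohort(cfg50)
  raw <- vapply(co$profiles, function(p) p$duration_raw, 0)
  sz <- cfg50$subject_size_distribution
  qs <- qlnorm(seq(0.2, 0.8, by = 0.2), sz$meanlog, sz$sdlog)
  obs <- table(cut(raw, c(0, qs, Inf)))
  ht <- suppressWarnings(chisq.test(as.vector(obs), p = rep(0.2, 5)))
  expect_gt(ht$p.value, 0.01)
})

test_that("reject-material subjects sit above the systolic plausibility range", {
  co <- generate_cohort(cohort_config(n_subjects = 4, seed = 2,
                                      fraction_reject_material = 1))
  for (p in co$profiles) expect_gt(p$base_sbp, 165)
})

test_that("rPPG reference BP uses an inclusive one-minute grid", {
  p <- quiet_profile("R1", record_duration = 7200, seed = 6)
  tr <- generate_rppg_trace(p, fs = 4, pulse_strength = 0.05)
  expect_equal(nrow(tr$reference), 121)  # 0..120 min inclusive
  expect_equal(tr$reference$time_s, seq(0, 7200, by = 60))
  expect_error(generate_rppg_trace(p, fs = 0), "positive")
})

test_that("a pulse-free noiseless trace yields a POS output with zero variance", {
  p <- quiet_profile("R0", record_duration = 60, seed = 5)
  tr <- generate_rppg_trace(p, fs = 32, pulse_strength = 0)
  out <- pos_extract(tr$rgb, 32)
  expect_lt(stats::var(out), 1e-20)
})

test_that("the embedded rPPG pulse frequency is recoverable after POS", {
  p <- quiet_profile("R2", base_hr = 66, record_duration = 90, seed = 8)
  tr <- generate_rppg_trace(p, fs = 32, pulse_strength = 0.1)
  pulse <- pos_extract(tr$rgb, 32)
  f <- estimate_heart_rate(pulse, 32) / 60
  expect_lt(abs(f - 1.1), 0.03)
})

test_that("inter-subject beat distance exceeds intra-subject distance", {
  # leakage substrate: same vitals, different morphology offsets
  mk <- function(id, off, seed) {
    generate_subject_record(subject_profile(
      id, base_hr = 60, base_sbp = 120, base_dbp = 70,
      bp_drift_amplitude = 0, hr_jitter_sd = 0, noise_sd = 0.02,
      morphology_offset = off, record_duration = 30, seed = seed))
  }
  off_a <- c(0.01, 0.05, 0.02, 0.04)
  off_b <- c(-0.01, -0.08, -0.03, -0.05)
  a1 <- mk("A", off_a, 1); a2 <- mk("A", off_a, 2)
  b1 <- mk("B", off_b, 3)
  beat <- function(r, k) r$ppg[(k * 125 + 1):(k * 125 + 125)]
  l2 <- function(u, v) sqrt(mean((u - v)^2))
  intra <- mean(vapply(1:20, function(k) l2(beat(a1, k), beat(a2, k)), 0))
  inter <- mean(vapply(1:20, function(k) l2(beat(a1, k), beat(b1, k)), 0))
  expect_gt(inter, intra)
})
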