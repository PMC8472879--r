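make_abp <- function(sbp = 120, dbp = 60, hr = 60, dur = 7, fs = 125,
                     noise_sd = 0) {
  p <- subject_profile("L", base_hr = hr, base_sbp = sbp, base_dbp = dbp,
                       bp_drift_amplitude = 0, hr_jitter_sd = 0,
                       noise_sd = 0, record_duration = max(10, dur),
                       seed = 1, allow_implausible = TRUE)
  abp <- generate_subject_record(p)$abp[1:(dur * fs)]
  if (noise_sd > 0) abp <- abp + rnorm(length(abp), sd = noise_sd)
  abp
}

test_that("extrema detection finds one peak and trough per beat", {
  abp <- make_abp(120, 60, 60, 7)
  ex <- detect_abp_extrema(abp, 125, 60)
  expect_equal(nrow(ex$systolic), 7)
  expect_true(all(abs(ex$systolic$value - 120) <= 0.5))
  expect_true(all(abs(ex$diastolic$value - 60) <= 0.5))
  expect_true(all(diff(ex$systolic$index) > 0))

  set.seed(2)
  noisy <- make_abp(120, 60, 60, 7, noise_sd = 1)
  exn <- detect_abp_extrema(noisy, 125, 60)
  expect_equal(nrow(exn$systolic), 7)
  expect_true(all(abs(exn$systolic$value - 120) <= 3))

  ramp <- seq(60, 120, length.out = 500)
  expect_true(detect_abp_extrema(ramp, 125, 60)$too_few_peaks)
})

test_that("window labels are medians with inclusive plausibility bounds", {
  lab <- label_window(make_abp(120, 70, 72, 7), 125, hr_hint = 72)
  expect_true(lab$valid)
  expect_equal(lab$sbp, 120, tolerance = 0.05)
  expect_equal(lab$dbp, 70, tolerance = 0.05)
  expect_equal(lab$median_hr, 72, tolerance = 1)

  hi <- label_window(make_abp(170, 70, 72, 7), 125, hr_hint = 72)
  expect_false(hi$valid)
  expect_equal(hi$reject_reason, "sbp_range")

  # exact boundary values stay valid (inclusive bounds)
  expect_equal(check_plausibility(165, 80, 140), "none")
  expect_equal(check_plausibility(75, 40, 50), "none")
  expect_equal(check_plausibility(165.01, 80, 140), "sbp_range")

  ramp <- seq(60, 120, length.out = 500)
  bad <- label_window(ramp, 125)
  expect_false(bad$valid)
  expect_equal(bad$reject_reason, "too_few_peaks")
})

test_that("the median label resists one-sided corruption of a minority of beats", {
  peaks <- c(118, 120, 122, 121, 119, 120, 120)
  expect_equal(median(peaks), 120)
  # push the floor((n-1)/2) largest values arbitrarily far out on their own
  # side: the median is unmoved
  corrupted <- peaks
  top3 <- order(peaks, decreasing = TRUE)[1:3]
  corrupted[top3] <- corrupted[top3] + 100
  expect_equal(median(corrupted), median(peaks))
  corrupted[top3] <- corrupted[top3] + 1e6
  expect_equal(median(corrupted), median(peaks))
})

test_that("rule ordering flags a doubly-violating label with the first rule", {
  expect_equal(check_plausibility(170, 90, 150), "sbp_range")
  expect_equal(check_plausibility(120, 90, 150), "dbp_range")
  expect_equal(check_plausibility(120, 70, 150), "hr_range")
  expect_equal(check_plausibility(120, 70, NA_real_), "none")
})

test_that("plausibility filtering matches brute-force rule application", {
  set.seed(6)
  n <- 1000
  sbp <- runif(n, 60, 190)
  dbp <- runif(n, 30, 95)
  hr <- runif(n, 35, 170)
  got <- check_plausibility(sbp, dbp, hr)
  # independent elementwise oracle, first-violated-rule order sbp, dbp, hr
  want <- vapply(seq_len(n), function(i) {
    if (sbp[i] < 75 || sbp[i] > 165) return("sbp_range")
    if (dbp[i] < 40 || dbp[i] > 80) return("dbp_range")
    if (hr[i] < 50 || hr[i] > 140) return("hr_range")
    "none"
  }, "")
  expect_identical(got, want)

  labels <- ppgbp:::new_bp_label(sbp, dbp, hr, 7L, got == "none", got)
  ws <- ppgbp:::new_window_set(
    matrix(rnorm(n * 10), n), data.frame(
      subject_id = "f", source_offset = seq_len(n), span = 10L,
      estimated_hr = 60, snr_db = 0, strategy = "const_time"),
    vector("list", n), 125, 125, windowing_config("const_time", 7))
  fl <- filter_labelled_windows(ws, labels)
  expect_equal(ppgbp:::n_windows(fl$windows), sum(want == "none"))
  expect_identical(fl$windows$meta$source_offset, which(want == "none"))
  expect_equal(unname(fl$counts["sbp_range"]), sum(want == "sbp_range"))
  expect_equal(unname(fl$counts["hr_range"]), sum(want == "hr_range"))
  # all-valid input is the identity
  ok <- labels[labels$valid, , drop = FALSE]
  ws_ok <- ppgbp:::subset_window_set(ws, which(labels$valid))
  fl2 <- filter_labelled_windows(ws_ok, ok)
  expect_equal(ppgbp:::n_windows(fl2$windows), nrow(ok))
})

test_that("labels recover generator ground truth on a drift-free cohort", {
  co <- generate_cohort(cohort_config(
    n_subjects = 12, seed = 5,
    subject_size_distribution = list(meanlog = log(90), sdlog = 0.2,
                                     min_s = 60, max_s = 150),
    population = list(drift_amplitude_range = c(0, 0), hr_jitter_sd = 0,
                      noise_sd = 0.02)))
  hits <- 0L; total <- 0L
  for (id in names(co$records)) {
    ws <- preprocess_record(co$records[[id]],
                            windowing_config("const_beats", 7))
    if (!ppgbp:::n_windows(ws)) next
    labs <- label_windows(ws)
    pr <- co$profiles[[id]]
    ok <- abs(labs$sbp - pr$base_sbp) <= 1 & abs(labs$dbp - pr$base_dbp) <= 1
    hits <- hits + sum(ok); total <- total + nrow(labs)
  }
  expect_gt(total, 100)
  expect_gte(hits / total, 0.99)
})
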