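test_that("MAE is the mean absolute error per target", {
  y <- cbind(sbp = c(110, 130), dbp = c(70, 70))
  expect_equal(unname(mae(y, y)), c(0, 0))
  pred <- cbind(c(120, 120), c(70, 70))
  expect_equal(unname(mae(pred, y)), c(10, 0))
  set.seed(1)
  p2 <- cbind(rnorm(50, 120, 10), rnorm(50, 70, 5))
  y2 <- cbind(rnorm(50, 120, 10), rnorm(50, 70, 5))
  expect_equal(unname(mae(p2, y2)),
               c(mean(abs(p2[, 1] - y2[, 1])), mean(abs(p2[, 2] - y2[, 2]))))
  expect_error(mae(p2[1:3, ], y2), "mismatch")
})

test_that("bin-wise MAE uses half-open 10 mmHg bins anchored at the range floor", {
  b <- binwise_mae(numeric(0), numeric(0), c(75, 165))
  expect_equal(nrow(b), 9)
  expect_equal(b$bin_lo, seq(75, 155, by = 10))

  one <- binwise_mae(105, 100, c(75, 165))
  expect_equal(one$n[one$bin_lo == 95], 1)
  expect_equal(one$mae[one$bin_lo == 95], 5)
  expect_equal(sum(one$n), 1)

  # boundary membership: 165 falls in the final (closed) bin
  edge <- binwise_mae(c(160, 160), c(165, 155), c(75, 165))
  expect_equal(edge$n[edge$bin_lo == 155], 2)
  expect_error(binwise_mae(1, 1, c(75, 165), bin_width = 0), "positive")
})

test_that("the report's bin-weighted MAE aggregates to the overall MAE", {
  set.seed(2)
  n <- 400
  y <- cbind(sbp = runif(n, 76, 164), dbp = runif(n, 41, 79))
  pred <- y + matrix(rnorm(2 * n, 0, 6), n)
  rep1 <- evaluation_report(pred, y,
                            baseline = mean_regressor_fit(y))
  agg_sbp <- with(rep1$bins_sbp, sum(n * mae, na.rm = TRUE) / sum(n))
  expect_equal(agg_sbp, rep1$overall_mae_sbp, tolerance = 1e-9)
  agg_dbp <- with(rep1$bins_dbp, sum(n * mae, na.rm = TRUE) / sum(n))
  expect_equal(agg_dbp, rep1$overall_mae_dbp, tolerance = 1e-9)
  expect_equal(sum(rep1$bins_sbp$n), n)
})

test_that("the mean-regressor report equals its closed form", {
  set.seed(3)
  ytr <- cbind(sbp = runif(200, 80, 160), dbp = runif(200, 45, 78))
  yte <- cbind(sbp = runif(100, 80, 160), dbp = runif(100, 45, 78))
  base <- mean_regressor_fit(ytr)
  rep1 <- evaluation_report(predict_bp(base, yte), yte, baseline = base)
  expect_equal(rep1$overall_mae_sbp, mean(abs(yte[, 1] - mean(ytr[, 1]))),
               tolerance = 1e-9)
  expect_equal(rep1$baseline_mae_sbp, rep1$overall_mae_sbp,
               tolerance = 1e-12)
})

test_that("KS comparison flags a shifted distribution and not an identical one", {
  set.seed(4)
  a <- rnorm(100)
  same <- compare_error_distributions(a, a)
  expect_equal(same$statistic, 0)
  expect_false(same$significant)

  b <- rnorm(100) + 2
  shifted <- compare_error_distributions(a, b)
  expect_true(shifted$significant)

  # permutation oracle for the same KS statistic
  ks_stat <- function(u, v) {
    w <- sort(c(u, v))
    max(abs(ecdf(u)(w) - ecdf(v)(w)))
  }
  obs <- ks_stat(a, b)
  expect_equal(obs, unname(shifted$statistic), tolerance = 1e-12)
  pooled <- c(a, b)
  perm <- replicate(200, {
    idx <- sample(200, 100)
    ks_stat(pooled[idx], pooled[-idx])
  })
  p_perm <- mean(perm >= obs)
  expect_lt(p_perm, 0.05)
  expect_error(compare_error_distributions(1, 1:5), "at least 2")
})

test_that("degenerate paired designs return defined results instead of crashing", {
  base <- c(5, 6, 7, 8)
  shifted <- compare_error_distributions(base + 1, base, "paired_t")
  expect_true(shifted$significant)
  expect_true(is.infinite(shifted$statistic))
  expect_equal(shifted$p_value, 0)

  null <- compare_error_distributions(base, base, "paired_t")
  expect_false(null$significant)
  expect_equal(null$statistic, 0)
  expect_error(compare_error_distributions(1:4, 1:5, "paired_t"),
               "equal lengths")
})

test_that("the BHS-style grade thresholds at 85% within 10 mmHg", {
  expect_equal(bhs_grade(rep(0, 10)),
               list(proportion_within = 1, pass = TRUE))
  half <- bhs_grade(c(5, 15))
  expect_equal(half$proportion_within, 0.5)
  expect_false(half$pass)

  set.seed(5)
  errs <- abs(rnorm(1000, 0, 8))
  got <- bhs_grade(errs)$proportion_within
  expected <- 2 * pnorm(10, 0, 8) - 1
  ci <- 3 * sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(got - expected), ci)
  expect_error(bhs_grade(numeric(0)), "empty")
})

test_that("evaluation reports round-trip through JSON losslessly", {
  set.seed(6)
  n <- 120
  y <- cbind(sbp = runif(n, 76, 164), dbp = runif(n, 41, 79))
  pred <- y + matrix(rnorm(2 * n, 0, 5), n)
  rep1 <- evaluation_report(pred, y, baseline = mean_regressor_fit(y))
  path <- tempfile(fileext = ".json")
  write_report(rep1, path)
  rep2 <- read_report(path)
  expect_equal(rep2$overall_mae_sbp, rep1$overall_mae_sbp)
  expect_equal(rep2$bins_sbp$mae, rep1$bins_sbp$mae)
  expect_equal(rep2$bhs_dbp$proportion_within,
               rep1$bhs_dbp$proportion_within)
  expect_equal(rep2$n_test, rep1$n_test)
})
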