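toy_pool <- function(sizes, T = 20, seed = 1) {
  set.seed(seed)
  subject <- rep(names(sizes), unlist(sizes))
  n <- length(subject)
  offset <- unlist(lapply(sizes, seq_len))
  structure(list(
    x = matrix(rnorm(n * T), n),
    y = cbind(sbp = runif(n, 90, 160), dbp = runif(n, 45, 80)),
    subject = subject, offset = offset,
    id = paste0(subject, "@", offset)),
    class = "bp_window_pool")
}

test_that("capping limits each subject's contribution reproducibly", {
  pool <- toy_pool(list(A = 500, B = 3000))
  capped <- cap_subjects(pool, cap = 2000, seed = 1)
  tab <- table(capped$subject)
  expect_equal(unname(tab["A"]), 500)     # small subjects pass through
  expect_equal(unname(tab["B"]), 2000)    # large subjects capped exactly
  capped2 <- cap_subjects(pool, cap = 2000, seed = 1)
  expect_identical(capped$id, capped2$id)
  capped3 <- cap_subjects(pool, cap = 2000, seed = 2)
  expect_false(identical(capped$id, capped3$id))
})

test_that("non-mixed splits keep subject sets disjoint and exhaustive", {
  pool <- toy_pool(as.list(setNames(rep(40, 10), paste0("S", 1:10))))
  sp <- split_non_mixed(pool, 6, 2, 2, seed = 3)
  a <- sp$subject_assignment
  expect_setequal(names(a), paste0("S", 1:10))
  expect_equal(sum(a == "train"), 6)
  expect_equal(sum(a == "val"), 2)
  expect_equal(sum(a == "test"), 2)
  expect_length(intersect(unique(sp$train$subject), unique(sp$test$subject)), 0)
  expect_length(intersect(unique(sp$train$subject), unique(sp$val$subject)), 0)
  sp2 <- split_non_mixed(pool, 6, 2, 2, seed = 3)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_non_mixed(pool, 9, 2, 2, seed = 1), "requested")
})

test_that("over-requested sample counts scale down proportionally", {
  pool <- toy_pool(as.list(setNames(rep(30, 10), paste0("S", 1:10))))
  expect_warning(
    sp <- split_non_mixed(pool, 6, 2, 2, n_train = 1e6, n_val = 2.5e5,
                          n_test = 2.5e5, seed = 1),
    "scaled down")
  # requested 4:1:1 ratio preserved after scale-down
  expect_equal(ppgbp:::pool_size(sp$train) / ppgbp:::pool_size(sp$val), 4,
               tolerance = 0.35)
  expect_lte(ppgbp:::pool_size(sp$train), 180)
})

test_that("mixed splits cut shuffled samples by the configured fractions", {
  pool <- toy_pool(as.list(setNames(rep(60, 15), paste0("S", 1:15))))
  sp <- split_mixed(pool, seed = 2)
  n <- length(pool$subject)
  expect_equal(ppgbp:::pool_size(sp$train), floor(2 / 3 * n))
  expect_equal(ppgbp:::pool_size(sp$val), floor(n / 6))
  expect_length(intersect(sp$train$id, sp$test$id), 0)
  # leakage: nearly every test sample's subject also appears in training
  leaked <- mean(sp$test$subject %in% unique(sp$train$subject))
  expect_gte(leaked, 0.99)
  sp2 <- split_mixed(pool, seed = 2)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_mixed(pool, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("full-scale mixed arithmetic: 750 x 2000 samples cut 1M/250k/250k", {
  n <- 750 * 2000
  expect_equal(floor(2 / 3 * n), 1e6)
  expect_equal(floor(n / 6), 250000)
})

test_that("mixed and non-mixed splits draw from similar label distributions", {
  pool <- toy_pool(as.list(setNames(rep(80, 20), paste0("S", 1:20))))
  nm <- split_non_mixed(pool, 12, 4, 4, seed = 1)
  mx <- split_mixed(pool, seed = 1)
  ks <- suppressWarnings(stats::ks.test(nm$train$y[, 1], mx$train$y[, 1]))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("personalization partitions split 20/40/40 in temporal order", {
  pool <- toy_pool(list(A = 100))
  part <- make_personalization_partition(pool, "first_20", seed = 1)
  expect_equal(sort(part$idx$calibration), 1:20)
  expect_equal(sort(part$idx$test), 61:100)
  expect_equal(sort(part$idx$spare), 21:60)

  rnd <- make_personalization_partition(pool, "random_20", seed = 1)
  # identical test windows across strategies; calibration from first20 u spare
  expect_identical(sort(rnd$idx$test), sort(part$idx$test))
  expect_length(rnd$idx$calibration, 20)
  expect_true(all(rnd$idx$calibration %in% 1:60))
  expect_length(intersect(rnd$idx$calibration, rnd$idx$test), 0)

  small <- make_personalization_partition(toy_pool(list(B = 10)), "first_20")
  expect_equal(ppgbp:::pool_size(small$calibration), 2)
  expect_equal(ppgbp:::pool_size(small$test), 4)
  expect_error(make_personalization_partition(toy_pool(list(C = 9)),
                                              "first_20"), "at least 10")
})

test_that("every split construction enforces the disjointness invariants", {
  pool <- toy_pool(as.list(setNames(rep(25, 8), paste0("S", 1:8))))
  for (seed in 1:3) {
    sp <- split_non_mixed(pool, 4, 2, 2, seed = seed)
    subs <- list(unique(sp$train$subject), unique(sp$val$subject),
                 unique(sp$test$subject))
    expect_length(Reduce(intersect, subs), 0)
    mx <- split_mixed(pool, seed = seed)
    ids <- c(mx$train$id, mx$val$id, mx$test$id)
    expect_equal(anyDuplicated(ids), 0)
  }
})
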