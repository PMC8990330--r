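test_that("Savitzky-Golay smoothing reproduces low-degree polynomials exactly", {
  t <- seq_len(10080)
  poly <- 2 + 0.5 * t - 3e-4 * t^2 + 1e-8 * t^3
  out <- smooth_week(poly, window = 21L, polyorder = 3L)
  expect_lt(max(abs(out - poly)), 1e-9 * max(abs(poly)))

  const <- rep(100, 10080)
  expect_equal(smooth_week(const), const, tolerance = 1e-12)
})

test_that("smoothing is linear and validates its window", {
  withr::with_seed(1, {
    x <- rnorm(10080); y <- rnorm(10080)
  })
  lhs <- smooth_week(2 * x + 3 * y)
  rhs <- 2 * smooth_week(x) + 3 * smooth_week(y)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(smooth_week(x, window = 20L), "odd")
  expect_error(smooth_week(x, window = 3L, polyorder = 3L), "exceed")
  expect_error(smooth_week(rnorm(11), window = 21L), "shorter")
})

test_that("smoothing beats an equal-window moving mean on bursty activity", {
  # activity-like signal with sharp bursts: a moving mean flattens the
  # bursts, the polynomial filter preserves them
  t <- seq_len(10080)
  centers <- seq(90, 10080, by = 180)
  signal <- 30 + Reduce(`+`, lapply(centers, function(c0)
    150 * exp(-(t - c0)^2 / (2 * 8^2))))
  noisy <- withr::with_seed(5, signal + rnorm(10080, sd = 20))
  sg <- smooth_week(noisy, window = 21L, polyorder = 3L)
  mm <- as.numeric(stats::filter(noisy, rep(1 / 21, 21), sides = 2))
  keep <- !is.na(mm)
  snr <- function(est) sum(signal[keep]^2) / sum((est[keep] - signal[keep])^2)
  expect_gt(snr(sg), snr(mm))
})

test_that("week reshaping places minutes at (day, hour, minute) and inverts", {
  flat <- seq_len(10080) - 1 # value = 0-based flat index
  arr <- reshape_week(flat)
  expect_identical(dim(arr), c(7L, 24L, 60L))
  expect_identical(arr[1, 1, 1], 0)                     # flat index 0
  expect_identical(arr[7, 24, 60], 10079)               # flat index 10,079
  expect_identical(arr[3, 5, 10], (3 - 1) * 1440 + (5 - 1) * 60 + 10 - 1)
  x <- withr::with_seed(2, rnorm(10080))
  expect_identical(flatten_week(reshape_week(x)), x)
  expect_error(reshape_week(rnorm(100)), "10080")

  mat <- withr::with_seed(3, matrix(rnorm(3 * 10080), 3))
  tens <- reshape_cohort(mat)
  expect_identical(tens[2, , , ], reshape_week(mat[2, ]))
  expect_identical(actiphen:::flatten_tensor(tens), mat)
})

test_that("per-minute standardization yields mean 0 / SD 1 across participants", {
  m <- matrix(c(1, 3), 2, 1)
  expect_identical(unname(standardize_per_minute(m)[, 1]), c(-1, 1))
  cohort <- withr::with_seed(4, matrix(rexp(50 * 200), 50, 200))
  cohort[, 7] <- 42 # constant minute maps to zeros
  z <- standardize_per_minute(cohort)
  expect_lt(max(abs(colMeans(z))), 1e-8)
  pop_sd <- sqrt(colMeans(sweep(z, 2L, colMeans(z))^2))
  expect_lt(max(abs(pop_sd[-7] - 1)), 1e-8)
  expect_identical(unname(z[, 7]), rep(0, 50))
  expect_error(standardize_per_minute(cohort[1, , drop = FALSE]), "at least 2")
})

test_that("standardization commutes with participant permutation and supports
          leakage-safe statistics", {
  cohort <- withr::with_seed(6, matrix(rnorm(30 * 100, mean = 5), 30, 100))
  perm <- withr::with_seed(7, sample.int(30))
  z_then_perm <- standardize_per_minute(cohort)[perm, ]
  perm_then_z <- standardize_per_minute(cohort[perm, ])
  expect_equal(z_then_perm, perm_then_z, tolerance = 1e-12,
               ignore_attr = TRUE)

  z_safe <- standardize_per_minute(cohort, train_idx = 1:20)
  ctr <- colMeans(cohort[1:20, ])
  expect_equal(attr(z_safe, "center"), ctr)
  # held-out rows are scaled by training statistics, not their own
  expect_false(isTRUE(all.equal(colMeans(z_safe[21:30, ]),
                                rep(0, 100), tolerance = 0.01)))
})

test_that("fold plans stratify the cohort's class balance", {
  labels <- c(rep(1L, 266), rep(0L, 6896))
  plan <- make_fold_plan(labels, test_fraction = 0.2, k = 10L, seed = 9L)
  expect_true(sum(labels[plan$test]) %in% c(53L, 54L))
  cv_idx <- setdiff(seq_along(labels), plan$test)
  for (f in plan$folds) {
    expect_length(intersect(f$train, plan$test), 0L)
    expect_length(intersect(f$validation, f$train), 0L)
    expect_setequal(c(f$train, f$validation), cv_idx)
  }
  # validation folds partition the CV set
  all_val <- sort(unlist(lapply(plan$folds, `[[`, "validation")))
  expect_identical(all_val, sort(cv_idx))
  # stratification deviation at most 1 participant per class per fold
  pos_cv <- sum(labels[cv_idx])
  for (f in plan$folds) {
    expect_lte(abs(sum(labels[f$validation]) - pos_cv / 10), 1)
  }
})

test_that("balanced labels split into exactly proportional folds", {
  labels <- rep(c(1L, 0L), each = 100L)
  plan <- make_fold_plan(labels, 0.2, k = 10L, seed = 2L)
  expect_identical(sum(labels[plan$test]), 20L)
  for (f in plan$folds) {
    expect_identical(sum(labels[f$validation]), 8L)    # 10% of each class
    expect_identical(sum(labels[f$validation] == 0L), 8L)
  }
  plan2 <- make_fold_plan(labels, 0.2, k = 10L, seed = 2L)
  expect_identical(plan, plan2)
  expect_error(make_fold_plan(c(rep(1L, 5), rep(0L, 100)), k = 10L),
               "too few")
})

test_that("class weights reproduce the cohort class fractions", {
  labels <- c(rep(1L, 266), rep(0L, 6896))
  cw <- compute_class_weights(labels)
  expect_equal(cw$weight_negative, 266 / 7162, tolerance = 1e-12)
  expect_equal(cw$weight_positive, 6896 / 7162, tolerance = 1e-12)
  expect_equal(round(cw$weight_negative, 5), 0.03714)
  expect_equal(round(cw$weight_positive, 5), 0.96286)

  expect_equal(unclass(compute_class_weights(rep(c(0, 1), 10))),
               list(weight_negative = 0.5, weight_positive = 0.5))
  cw2 <- compute_class_weights(c(1L, rep(0L, 9)))
  expect_equal(cw2$weight_negative, 0.1)
  expect_equal(cw2$weight_positive, 0.9)
  expect_error(compute_class_weights(rep(1L, 5)), "both classes")
})
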