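test_that("group mean activity summarizes participant means with CIs", {
  act <- matrix(100, 6, 10080)
  labels <- c(1, 1, 0, 0, 0, 0)
  gm <- group_mean_activity(act, labels)
  expect_equal(gm$mean, c(100, 100))
  expect_equal(gm$ci_high - gm$ci_low, c(0, 0))
  expect_identical(gm$n, c(2L, 4L))

  withr::with_seed(41, act2 <- matrix(rexp(8 * 10080, rate = 0.01), 8))
  labels2 <- c(1, 0, 1, 0, 1, 0, 0, 0)
  gm2 <- group_mean_activity(act2, labels2)
  # invariant to participant order
  perm <- c(5, 2, 7, 1, 3, 8, 4, 6)
  gm_perm <- group_mean_activity(act2[perm, ], labels2[perm])
  expect_equal(gm2, gm_perm)
  # linear in a global rescaling
  gm_scaled <- group_mean_activity(3 * act2, labels2)
  expect_equal(gm_scaled$mean, 3 * gm2$mean)
  expect_equal(gm_scaled$ci_low, 3 * gm2$ci_low)
  expect_error(group_mean_activity(act, rep(1, 6)), "non-empty")
})

test_that("interval slopes recover exact lines with zero-width CIs", {
  # every participant's day is y = 2t + 5
  day <- 2 * (0:1439) + 5
  act <- matrix(rep(day, 7), 8, 10080, byrow = TRUE)
  curve <- group_curve(act, c(1, 1, 1, 1, 0, 0, 0, 0), smooth = FALSE)
  sl <- interval_slope(curve, "morning", n_boot = 100L, seed = 2L)
  expect_equal(sl$slope, c(2, 2), tolerance = 1e-9)
  expect_equal(sl$ci_high - sl$ci_low, c(0, 0), tolerance = 1e-12)
  ev <- interval_slope(curve, "evening", n_boot = 50L, seed = 2L)
  expect_equal(ev$slope, c(2, 2), tolerance = 1e-9)
  expect_error(interval_slope(curve, c(10, 12)), "3 minutes")
})

test_that("noiseless planted profiles yield exact slope ratios", {
  p_ctrl <- actiphen:::profile_from_mean(168.8, 0.97, -0.76)
  p_exp <- actiphen:::profile_from_mean(0.71 * 168.8, 0.75 * 0.97,
                                        0.51 * -0.76)
  act <- rbind(matrix(rep(p_exp$values, 7), 3, 10080, byrow = TRUE),
               matrix(rep(p_ctrl$values, 7), 3, 10080, byrow = TRUE))
  labels <- c(1, 1, 1, 0, 0, 0)
  curve <- group_curve(act, labels, smooth = FALSE)
  sl <- interval_slope(curve, "morning", n_boot = 50L, seed = 1L)
  s_exp <- sl$slope[sl$group == "exposed"]
  s_ctl <- sl$slope[sl$group == "control"]
  expect_equal(s_exp, 0.75 * 0.97, tolerance = 1e-9)
  expect_equal(s_exp / s_ctl, 0.75, tolerance = 1e-9)
  ev <- interval_slope(curve, "evening", n_boot = 50L, seed = 1L)
  expect_equal(ev$slope[ev$group == "exposed"] /
                 ev$slope[ev$group == "control"], 0.51, tolerance = 1e-9)
})

test_that("bootstrap slope intervals cover the planted slope", {
  prof <- actiphen:::profile_from_mean(168.8, 0.97, -0.76)
  nm <- noise_model()
  n_rep <- 150L
  n_per <- 25L
  covered <- withr::with_seed(43, {
    vapply(seq_len(n_rep), function(r) {
      weeks <- actiphen:::draw_weeks(prof, nm, 2 * n_per)
      curve <- group_curve(weeks, rep(c(1, 0), each = n_per),
                           smooth = FALSE)
      sl <- interval_slope(curve, "morning", n_boot = 200L, seed = r)
      s <- sl[sl$group == "exposed", ]
      s$ci_low <= 0.97 && 0.97 <= s$ci_high
    }, logical(1))
  })
  expect_gte(mean(covered), 0.9)
})

test_that("Welch t from summary statistics matches t.test and flags the
          published PHQ-9 contrast", {
  withr::with_seed(44, {
    a <- rnorm(40, 5, 2)
    b <- rnorm(60, 4, 3)
  })
  ref <- t.test(a, b)
  got <- welch_t_summary(mean(a), sd(a), 40, mean(b), sd(b), 60)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  # published cohort PHQ-9 summary: 4.26 (4.27) n=266 vs 2.68 (2.82) n=6896
  phq <- welch_t_summary(4.26, 4.27, 266, 2.68, 2.82, 6896)
  expect_lt(phq$p_value, 0.001)
  expect_gt(phq$statistic, 0)
})

test_that("demographic tests run the standard chi-squared and Welch t
          comparisons", {
  # sex split replicating the published cohort table: 186/80 exposed,
  # 3520/3376 control
  sex <- c(rep("female", 186), rep("male", 80),
           rep("female", 3520), rep("male", 3376))
  labels <- c(rep(1L, 266), rep(0L, 6896))
  withr::with_seed(45, {
    demo <- tibble::tibble(
      age = rnorm(7162, 35 + 10 * labels, 10),
      sex = sex,
      race = sample(c("White", "Black", "Other"), 7162, TRUE))
    phq9 <- rnorm(7162, 2.7 + 1.6 * labels, 3)
    phq9[sample(7162, 2000)] <- NA
  })
  out <- demographic_tests(demo, phq9, labels)
  expect_identical(out$variable, c("sex", "race", "age", "phq9"))
  expect_lt(out$p_value[out$variable == "sex"], 0.001)
  expect_lt(out$p_value[out$variable == "age"], 0.001)
  expect_lt(out$p_value[out$variable == "phq9"], 0.001)
  expect_true(out$significant[out$variable == "sex"])
})

test_that("identical group distributions give a null chi-squared", {
  demo <- tibble::tibble(
    age = rep(c(20, 40), 40),
    sex = rep(c("female", "male"), 40),
    race = rep(c("White", "Black"), 40))
  labels <- rep(c(1L, 0L), each = 40L)
  # both groups have exactly the same sex and race composition
  out <- demographic_tests(demo, rep(c(3, 5), 40), labels)
  sex_row <- out[out$variable == "sex", ]
  expect_equal(sex_row$statistic, 0, tolerance = 1e-12)
  expect_equal(sex_row$p_value, 1)
  expect_false(sex_row$significant)
})

test_that("degenerate contingency tables are rejected with the table
          attached", {
  demo <- tibble::tibble(
    age = rnorm(20),
    sex = factor(rep("female", 20), levels = c("female", "male")),
    race = rep(c("White", "Black"), 10))
  err <- tryCatch(
    demographic_tests(demo, rnorm(20), rep(c(1L, 0L), 10)),
    error = function(e) e)
  expect_match(conditionMessage(err), "zero expected")
  expect_true(!is.null(err$table))
})
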