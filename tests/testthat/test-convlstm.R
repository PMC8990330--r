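tiny_config <- function(...) {
  do.call(conv_lstm_config, utils::modifyList(
    list(filters = c(3L, 2L), kernel = 3L, pool = 2L, dropout_rate = 0,
         dense = 4L, seed = 7L), list(...)))
}

test_that("backpropagation matches finite-difference gradients", {
  model <- build_model(tiny_config(), with_phq9 = TRUE)
  withr::with_seed(42, {
    B <- 3L
    tensor <- array(rnorm(B * 7 * 24 * 60), dim = c(B, 7, 24, 60))
    phq <- rnorm(B)
  })
  y <- c(1, 0, 1); w <- c(0.9, 0.1, 0.9)
  X <- actiphen:::tensor_batch(tensor, 1:3)
  loss_at <- function(theta) {
    m <- model
    m$params <- actiphen:::unflatten_params(theta, model$params)
    fwd <- actiphen:::net_fwd(m, X, phq9 = phq)
    actiphen:::weighted_bce(fwd$prob, y, w)
  }
  theta <- actiphen:::flatten_params(model$params)
  fwd <- actiphen:::net_fwd(model, X, phq9 = phq)
  dz <- w * (fwd$prob - y) / 3
  bwd <- actiphen:::net_bwd(model, X, fwd, dz, need_dx = TRUE)
  g <- actiphen:::flatten_params(bwd$grads)
  idx <- withr::with_seed(99, sample(length(theta), 40))
  eps <- 1e-6
  for (i in idx) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    g_num <- (loss_at(tp) - loss_at(tm)) / (2 * eps)
    expect_equal(g[i], g_num, tolerance = 1e-4)
  }
  # input gradient at a few cells
  gin <- actiphen:::input_gradient(model, tensor, phq9 = phq)
  flat <- actiphen:::flatten_tensor(tensor)
  prob_sum <- function(f) {
    sum(actiphen:::net_fwd(model, actiphen:::tensor_batch(
      reshape_cohort(f), 1:3), phq9 = phq)$prob)
  }
  cells <- withr::with_seed(100,
                            cbind(sample(3, 6, replace = TRUE),
                                  sample(10080, 6)))
  for (r in seq_len(nrow(cells))) {
    f2 <- flat; f2[cells[r, 1], cells[r, 2]] <- f2[cells[r, 1], cells[r, 2]] + eps
    f3 <- flat; f3[cells[r, 1], cells[r, 2]] <- f3[cells[r, 1], cells[r, 2]] - eps
    g_num <- (prob_sum(f2) - prob_sum(f3)) / (2 * eps)
    expect_equal(gin[cells[r, 1], cells[r, 2]], g_num, tolerance = 1e-4)
  }
})

test_that("model building is deterministic and forward output is a probability", {
  m1 <- build_model(tiny_config())
  m2 <- build_model(tiny_config())
  expect_identical(m1$params, m2$params)
  tensor <- withr::with_seed(1, array(rnorm(2 * 7 * 24 * 60),
                                      dim = c(2, 7, 24, 60)))
  p1 <- predict_convlstm(m1, tensor)
  p2 <- predict_convlstm(m2, tensor)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  m3 <- build_model(tiny_config(seed = 8L))
  expect_false(identical(m1$params, m3$params))
})

test_that("PHQ-9 fusion adds exactly one dense fan-in of parameters", {
  base <- build_model(tiny_config(), with_phq9 = FALSE)
  fused <- build_model(tiny_config(), with_phq9 = TRUE)
  expect_identical(count_params(fused) - count_params(base),
                   tiny_config()$dense)
})

test_that("predictions are invariant to participant order in a batch", {
  model <- build_model(tiny_config())
  tensor <- withr::with_seed(2, array(rnorm(6 * 7 * 24 * 60),
                                      dim = c(6, 7, 24, 60)))
  p <- predict_convlstm(model, tensor)
  perm <- c(4, 1, 6, 2, 5, 3)
  p_perm <- predict_convlstm(model, tensor[perm, , , , drop = FALSE])
  expect_equal(p_perm, p[perm], tolerance = 1e-6)
})

test_that("the weighted loss equals hand-computed weighted cross-entropy", {
  p <- c(0.9, 0.2, 0.6)
  y <- c(1, 0, 0)
  w <- c(0.96, 0.04, 0.04)
  hand <- -(w[1] * log(0.9) + w[2] * log(0.8) + w[3] * log(0.4)) / 3
  expect_equal(actiphen:::weighted_bce(p, y, w), hand, tolerance = 1e-6)
})

test_that("cross-validated training is seeded and reproducible", {
  pw <- planted_window_cohort(n = 30L, n_pos = 10L, seed = 9L)
  tensor <- reshape_cohort(standardize_per_minute(pw$activity))
  plan <- make_fold_plan(pw$labels, 0.2, k = 2L, seed = 4L)
  cfg <- conv_lstm_config(filters = c(2L, 2L), epochs = 1L, patience = 1L,
                          dropout_rate = 0.2, dense = 4L, seed = 11L)
  fit1 <- train_cv(tensor, pw$labels, plan, config = cfg)
  fit2 <- train_cv(tensor, pw$labels, plan, config = cfg)
  expect_identical(fit1$cv_predictions, fit2$cv_predictions)
  expect_identical(fit1$test_predictions, fit2$test_predictions)
  expect_true(all(fit1$cv_predictions$probability >= 0 &
                    fit1$cv_predictions$probability <= 1))
  # ensemble test predictions are the fold-model average
  per_fold <- dplyr::filter(fit1$test_predictions, fold > 0)
  ens <- dplyr::filter(fit1$test_predictions, fold == 0)
  avg <- tapply(per_fold$probability, per_fold$index, mean)
  expect_equal(as.numeric(avg[as.character(ens$index)]), ens$probability)
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_identical(nrow(glance(fit1)), 1L)
})

test_that("PHQ-9 imputation fills from demographics without touching observed", {
  n <- 300L
  withr::with_seed(14, {
    demo <- tibble::tibble(
      age = runif(n, 10, 80),
      sex = sample(c("female", "male"), n, TRUE),
      race = sample(c("White", "Black", "Other"), n, TRUE))
    truth <- pmin(pmax(round(0.25 * demo$age + rnorm(n, sd = 1.5)), 0), 27)
    phq <- as.numeric(truth)
    # missing-at-random given age: younger scores missing more often
    miss <- runif(n) < plogis(2 - 0.06 * demo$age)
    phq[miss] <- NA
  })
  expect_identical(impute_phq9(as.numeric(truth), demo), as.numeric(truth))
  imp <- impute_phq9(phq, demo)
  expect_identical(imp[!is.na(phq)], phq[!is.na(phq)])
  expect_true(all(imp >= 0 & imp <= 27))
  rmse <- function(est) sqrt(mean((est[miss] - truth[miss])^2))
  mean_imp <- phq
  mean_imp[miss] <- mean(phq, na.rm = TRUE)
  expect_lt(rmse(imp), rmse(mean_imp))
  expect_error(impute_phq9(rep(NA_real_, 3),
                           demo[1:3, ]), "all PHQ-9")
})

test_that("out-of-range imputations are clipped and reported", {
  demo <- tibble::tibble(age = c(10, 20, 30, 40, 300),
                         sex = rep("female", 5),
                         race = rep("White", 5))
  phq <- c(5, 10, 15, 20, NA) # strong age slope extrapolates past 27
  expect_message(imp <- impute_phq9(phq, demo), "clipped")
  expect_identical(unname(imp[5]), 27)
})
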