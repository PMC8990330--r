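# Reference series for the frozen decomposition oracle: a sinusoid on a
# linear trend, length 64. Expected coefficients were computed once with an
# independent reference implementation of the Daubechies DWT and frozen.
oracle_series <- function() sin(2 * pi * (0:63) / 16) + 0.1 * (0:63)

test_that("single-level db4 analysis matches the frozen reference", {
  x <- oracle_series()
  dec <- wavelet_decompose(x, levels = 1L, wavelet = "db4", mode = "symmetric")
  expect_length(dec$a1, 35L)
  expect_length(dec$d1, 35L)
  expect_equal(dec$a1[1:5],
               c(1.9801594490523895, 1.2666576403570646, -0.003275365415290471,
                 0.6966457085065376, 1.7369921021044874), tolerance = 1e-12)
  expect_equal(dec$d1[1:5],
               c(0.021574186636703855, 0.03406006475738311,
                 -0.039587966042152575, -0.011508512273881537,
                 -0.0072877783261449045), tolerance = 1e-12)
  expect_equal(sum(dec$a1), 148.07552622475473, tolerance = 1e-10)
  expect_equal(sum(dec$d1), 0.013313554073689449, tolerance = 1e-10)

  per <- wavelet_decompose(x, levels = 1L, wavelet = "db4", mode = "periodic")
  expect_length(per$a1, 32L)
  expect_equal(per$a1[1:3],
               c(8.815266719038428, 1.4895892471678198, 1.2937084170404087),
               tolerance = 1e-12)
  expect_equal(sum(per$a1), 142.55272708720798, tolerance = 1e-10)
  expect_equal(sum(per$d1), 2.2627416997969556, tolerance = 1e-10)
})

test_that("multilevel decomposition matches frozen subband sums and energies", {
  x <- oracle_series()
  dec <- wavelet_decompose(x, levels = 3L, wavelet = "db4", mode = "symmetric")
  expect_identical(lengths(dec),
                   c(d1 = 35L, d2 = 21L, d3 = 14L, a3 = 14L))
  expect_equal(sum(dec$a3), 101.37049863266014, tolerance = 1e-9)
  expect_equal(sum(dec$a3^2), 1153.2316855647891, tolerance = 1e-9)
  expect_equal(sum(dec$d3^2), 30.918510195921616, tolerance = 1e-9)
  expect_equal(sum(dec$d2^2), 1.8940299709043642, tolerance = 1e-9)
  expect_equal(sum(dec$d1^2), 0.008131907167870501, tolerance = 1e-9)
})

test_that("detail coefficients vanish on constants and energy is conserved", {
  dec <- wavelet_decompose(rep(5, 512), levels = 6L)
  for (lev in 1:6) expect_lt(max(abs(dec[[paste0("d", lev)]])), 1e-10)

  x <- withr::with_seed(8, rnorm(1024))
  dec <- wavelet_decompose(x, levels = 6L, wavelet = "db4", mode = "periodic")
  energy <- sum(vapply(dec, function(c) sum(c^2), numeric(1)))
  expect_equal(energy, sum(x^2), tolerance = 1e-6)

  # subband lengths halve per level under symmetric padding:
  # len_l = floor((len_{l-1} + L - 1) / 2) with filter length L = 8
  sym <- wavelet_decompose(rnorm(10080), levels = 6L, mode = "symmetric")
  len <- 10080L
  for (lev in 1:6) {
    len <- (len + 7L) %/% 2L
    expect_identical(length(sym[[paste0("d", lev)]]), len)
  }
  expect_error(wavelet_decompose(rnorm(32), levels = 6L), "too short")
})

test_that("subband features match an independent brute-force recomputation", {
  set.seed(12)
  subbands <- list(d1 = rnorm(40), a1 = rexp(23))
  feats <- extract_features(subbands)
  for (nm in names(subbands)) {
    c0 <- subbands[[nm]]
    expect_equal(feats[[paste0(nm, "_mean")]], sum(c0) / length(c0))
    expect_equal(feats[[paste0(nm, "_pct25")]],
                 unname(quantile(c0, 0.25)))
    expect_equal(feats[[paste0(nm, "_pct75")]],
                 unname(quantile(c0, 0.75)))
    expect_equal(feats[[paste0(nm, "_sd")]], sqrt(var(c0)))
    expect_equal(feats[[paste0(nm, "_variance")]],
                 sum((c0 - mean(c0))^2) / (length(c0) - 1))
    p <- c0^2 / sum(c0^2)
    expect_equal(feats[[paste0(nm, "_entropy")]], -sum(p * log(p)))
    s <- sign(c0 - mean(c0))
    crossings <- sum(s[-1] * s[-length(s)] < 0)
    expect_equal(feats[[paste0(nm, "_mean_crossing_rate")]],
                 crossings / (length(c0) - 1))
    # internal identities
    expect_equal(feats[[paste0(nm, "_variance")]],
                 feats[[paste0(nm, "_sd")]]^2, tolerance = 1e-9)
    expect_lte(feats[[paste0(nm, "_pct25")]], feats[[paste0(nm, "_pct75")]])
  }
})

test_that("feature conventions hold at the boundaries", {
  # K equal-magnitude coefficients -> entropy log(K)
  feats <- extract_features(list(b = c(2, -2, 2, 2, -2, 2, 2, 2)))
  expect_equal(feats$b_entropy, log(8))
  # alternating signs cross at every step
  alt <- extract_features(list(b = rep(c(1, -1), 4)))
  expect_equal(alt$b_mean_crossing_rate, 1.0)
  # all-zero subband: entropy 0, crossings 0 by convention
  z <- extract_features(list(b = numeric(6)))
  expect_identical(z$b_entropy, 0)
  expect_identical(z$b_mean_crossing_rate, 0)
})

test_that("features are scale-equivariant", {
  x <- withr::with_seed(13, rnorm(2048, mean = 3))
  f1 <- wavelet_features(matrix(x, 1, dimnames = list("p")), levels = 4L)
  f2 <- wavelet_features(matrix(3.7 * x, 1, dimnames = list("p")), levels = 4L)
  for (band in c(paste0("d", 1:4), "a4")) {
    for (st in c("mean", "pct25", "pct75", "sd")) {
      expect_equal(f2[[paste0(band, "_", st)]],
                   3.7 * f1[[paste0(band, "_", st)]], tolerance = 1e-9)
    }
    expect_equal(f2[[paste0(band, "_variance")]],
                 3.7^2 * f1[[paste0(band, "_variance")]], tolerance = 1e-9)
    expect_equal(f2[[paste0(band, "_entropy")]],
                 f1[[paste0(band, "_entropy")]], tolerance = 1e-9)
    expect_equal(f2[[paste0(band, "_mean_crossing_rate")]],
                 f1[[paste0(band, "_mean_crossing_rate")]], tolerance = 1e-9)
  }
})

test_that("wavelet features run on full cohort weeks", {
  coh <- small_cohort()
  feats <- wavelet_features(smooth_week(coh$activity[1:4, , drop = FALSE]))
  expect_identical(dim(feats), c(4L, 50L)) # id + 7 stats x 7 subbands
  expect_true(all(is.finite(as.matrix(feats[-1]))))
})

test_that("the cross-validated baseline separates separable features", {
  set.seed(21)
  n <- 120L
  labels <- rep(c(1L, 0L), each = n / 2)
  feats <- tibble::tibble(participant_id = as.character(1:n),
                          f1 = labels * 10 + rnorm(n, sd = 0.1),
                          f2 = rnorm(n))
  plan <- make_fold_plan(labels, 0.2, k = 5L, seed = 1L)
  fit <- fit_wavelet_logistic(feats, labels, plan)
  expect_true(all(fit$fold_auc == 1.0))
  ens <- dplyr::filter(fit$test_predictions, fold == 0L)
  expect_equal(roc_auc(ens$probability, ens$label), 1.0)
})

test_that("the baseline is calibrated at the null", {
  set.seed(22)
  n <- 200L
  labels <- rep(c(1L, 0L), each = n / 2)
  feats <- tibble::tibble(participant_id = as.character(1:n))
  for (j in 1:8) feats[[paste0("f", j)]] <- rnorm(n)
  plan <- make_fold_plan(labels, 0.2, k = 5L, seed = 2L)
  fit <- fit_wavelet_logistic(feats, labels, plan)
  # null mean CV AUC: per-fold SE ~ 0.09 at 16+16 validation samples,
  # SE of the 5-fold mean ~ 0.04; 3 SE ~ 0.13
  expect_lt(abs(mean(fit$fold_auc) - 0.5), 0.13)
})

test_that("the baseline rejects non-finite features", {
  feats <- tibble::tibble(participant_id = c("a", "b"), f1 = c(1, NA))
  plan <- structure(list(test = 1L,
                         folds = list(list(train = 2L, validation = 2L)),
                         k = 1L, seed = 1L), class = "fold_plan")
  expect_error(fit_wavelet_logistic(feats, c(0L, 1L), plan), "non-finite")
})
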