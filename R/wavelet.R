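# Daubechies analysis filters (standard published coefficients).
DAUBECHIES_FILTERS <- list(
  db1 = list(lo = c(0.7071067811865476, 0.7071067811865476),
             hi = c(-0.7071067811865476, 0.7071067811865476)),
  db2 = list(lo = c(-0.12940952255126037, 0.2241438680420134,
                    0.8365163037378079, 0.48296291314453416),
             hi = c(-0.48296291314453416, 0.8365163037378079,
                    -0.2241438680420134, -0.12940952255126037)),
  db4 = list(lo = c(-0.010597401785069032, 0.0328830116668852,
                    0.030841381835560764, -0.18703481171909309,
                    -0.027983769416859854, 0.6308807679298589,
                    0.7148465705529157, 0.2303778133088965),
             hi = c(-0.2303778133088965, 0.7148465705529157,
                    -0.6308807679298589, -0.027983769416859854,
                    0.18703481171909309, 0.030841381835560764,
                    -0.0328830116668852, -0.010597401785069032))
)

conv_downsample <- function(ext, f, start, len) {
  z <- convolve(ext, rev(f), type = "open")
  z[seq(start, by = 2L, length.out = len)]
}

# single-level analysis step; `mode` follows the usual conventions:
# "symmetric" = half-sample reflection padding, "periodic" = periodization
# (odd lengths are extended by repeating the last sample; the transform is
# orthogonal, conserving energy exactly at even lengths)
dwt_step <- function(x, filt, mode) {
  L <- length(filt$lo)
  n <- length(x)
  if (mode == "symmetric") {
    ext <- c(x[(L - 1L):1L], x, x[n:(n - L + 2L)])
    len <- (n + L - 1L) %/% 2L
    start <- L + 1L
  } else {
    if (n %% 2L == 1L) { x <- c(x, x[n]); n <- n + 1L }
    ext <- c(tail(x, L), x, head(x, L))
    len <- n %/% 2L
    start <- L + L %/% 2L + 1L
  }
  list(approx = conv_downsample(ext, filt$lo, start, len),
       detail = conv_downsample(ext, filt$hi, start, len))
}

#' Multilevel Daubechies wavelet decomposition
#'
#' Cascaded analysis filter bank: `levels` detail subbands (finest `d1` to
#' coarsest `d<levels>`) plus the final approximation. With the
#' `"periodic"` boundary mode the transform is orthogonal, so the summed
#' squared coefficients equal the summed squared inputs (exactly at lengths
#' divisible by `2^levels`); `"symmetric"` padding (the default for feature
#' extraction) conserves energy only approximately but avoids wrap-around
#' artifacts in the subband statistics.
#'
#' @param week numeric series, length at least `2^levels`.
#' @param levels number of decomposition levels (default 6).
#' @param wavelet `"db4"` (default), `"db2"` or `"db1"`.
#' @param mode boundary mode, `"symmetric"` (default) or `"periodic"`.
#' @return Named list of subbands: `d1`, ..., `d<levels>`, `a<levels>`.
#' @export
wavelet_decompose <- function(week, levels = 6L, wavelet = "db4",
                              mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  filt <- DAUBECHIES_FILTERS[[wavelet]]
  if (is.null(filt)) stop("unknown wavelet: ", wavelet, call. = FALSE)
  if (length(week) < 2^levels)
    stop("series too short for ", levels, " decomposition levels", call. = FALSE)
  out <- vector("list", levels + 1L)
  names(out) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  a <- week
  for (lev in seq_len(levels)) {
    s <- dwt_step(a, filt, mode)
    out[[paste0("d", lev)]] <- s$detail
    a <- s$approx
  }
  out[[paste0("a", levels)]] <- a
  out
}

subband_entropy <- function(c) {
  e <- sum(c^2)
  if (e == 0) return(0)
  p <- c^2 / e
  p <- p[p > 0]
  -sum(p * log(p))
}

mean_crossing_rate <- function(c) {
  if (length(c) < 2L) return(0)
  s <- sign(c - mean(c))
  s <- s[s != 0]
  if (length(s) < 2L) return(0)
  sum(diff(s) != 0) / (length(c) - 1L)
}

#' Wavelet subband feature vector
#'
#' Seven statistics per subband: mean, 25th and 75th percentiles, Shannon
#' entropy of the normalized squared-coefficient distribution (natural
#' log), SD, variance, and the mean-crossing rate (fraction of steps at
#' which the mean-centered coefficients change sign). An all-zero subband
#' has entropy 0 and crossing rate 0 by convention.
#'
#' @param subbands list of coefficient vectors from [wavelet_decompose()].
#' @return A 1-row tibble with `7 * length(subbands)` columns named
#'   `<subband>_<statistic>`.
#' @export
extract_features <- function(subbands) {
  stopifnot(is.list(subbands), all(lengths(subbands) >= 2L))
  stat_one <- function(c) {
    q <- unname(quantile(c, c(0.25, 0.75), type = 7))
    tibble::tibble(mean = mean(c), pct25 = q[1], pct75 = q[2],
                   entropy = subband_entropy(c), sd = sd(c), variance = var(c),
                   mean_crossing_rate = mean_crossing_rate(c))
  }
  stats <- purrr::imap(subbands, function(c, nm) {
    s <- stat_one(c)
    names(s) <- paste0(nm, "_", names(s))
    s
  })
  dplyr::bind_cols(stats)
}

#' Wavelet feature matrix for a cohort
#'
#' Smooths nothing itself: pass smoothed activity. One row per participant,
#' 49 columns (7 statistics x 7 subbands at 6 levels).
#'
#' @param activity participants x 10,080 matrix (smoothed).
#' @param levels,wavelet,mode passed to [wavelet_decompose()].
#' @return Tibble with `participant_id` plus the feature columns.
#' @export
wavelet_features <- function(activity, levels = 6L, wavelet = "db4",
                             mode = "symmetric") {
  stopifnot(is.matrix(activity))
  rows <- lapply(seq_len(nrow(activity)), function(i) {
    extract_features(wavelet_decompose(activity[i, ], levels, wavelet, mode))
  })
  out <- dplyr::bind_rows(rows)
  ids <- rownames(activity)
  if (is.null(ids)) ids <- sprintf("P%05d", seq_len(nrow(activity)))
  dplyr::bind_cols(tibble::tibble(participant_id = ids), out)
}

#' Cross-validated logistic regression on wavelet features
#'
#' The movement-only baseline: per fold, features are z-scored on the
#' training participants, a logistic regression is fitted by weighted
#' maximum likelihood (per-observation class weights), and probabilities
#' are predicted for the validation fold and the held-out test set. The
#' held-out prediction reported per participant is the mean across the k
#' fold models.
#'
#' @param features tibble from [wavelet_features()] (or any numeric feature
#'   tibble with a `participant_id` column) — must be finite.
#' @param labels binary vector aligned with `features` rows.
#' @param fold_plan a [make_fold_plan()] object.
#' @param class_weights a [compute_class_weights()] object; computed from
#'   the training labels when `NULL`.
#' @return An object of class `wavelet_logistic_fit`: list with
#'   `cv_predictions` (tibble: participant row `index`, `fold`,
#'   `probability`, `label`), `test_predictions` (tibble: `index`, `fold`,
#'   `probability`, `label`; fold 0 = fold-averaged ensemble),
#'   `fold_auc` (numeric length k), and `class_weights`.
#' @export
fit_wavelet_logistic <- function(features, labels, fold_plan,
                                 class_weights = NULL) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  y <- as_label01(labels)
  X <- as.matrix(dplyr::select(tibble::as_tibble(features),
                               -dplyr::any_of("participant_id")))
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)
    stop("non-finite feature values at rows ",
         paste(unique(bad[, 1]), collapse = ", "), call. = FALSE)
  }
  if (is.null(class_weights))
    class_weights <- compute_class_weights(y[-fold_plan$test])
  cv_rows <- list(); test_prob <- matrix(NA_real_, length(fold_plan$test),
                                         fold_plan$k)
  fold_auc <- numeric(fold_plan$k)
  train_scores <- vector("list", fold_plan$k)
  for (i in seq_len(fold_plan$k)) {
    tr <- fold_plan$folds[[i]]$train
    va <- fold_plan$folds[[i]]$validation
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2L, sd)
    scl[scl == 0] <- 1
    Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
    dat <- data.frame(y = y[tr], Z[tr, , drop = FALSE])
    w <- sample_weights(y[tr], class_weights)
    fit <- suppressWarnings(glm(y ~ ., data = dat, family = binomial(),
                                weights = w))
    pv <- suppressWarnings(
      predict(fit, newdata = data.frame(Z[va, , drop = FALSE]), type = "response"))
    pt <- suppressWarnings(
      predict(fit, newdata = data.frame(Z[fold_plan$test, , drop = FALSE]),
              type = "response"))
    cv_rows[[i]] <- tibble::tibble(index = va, fold = i, probability = unname(pv),
                                   label = y[va])
    test_prob[, i] <- pt
    fold_auc[i] <- roc_auc(pv, y[va])
    train_scores[[i]] <- unname(fit$fitted.values)
  }
  test_predictions <- dplyr::bind_rows(
    lapply(seq_len(fold_plan$k), function(i)
      tibble::tibble(index = fold_plan$test, fold = i,
                     probability = test_prob[, i], label = y[fold_plan$test])),
    tibble::tibble(index = fold_plan$test, fold = 0L,
                   probability = rowMeans(test_prob), label = y[fold_plan$test])
  )
  structure(list(cv_predictions = dplyr::bind_rows(cv_rows),
                 test_predictions = test_predictions,
                 fold_auc = fold_auc, train_scores = train_scores,
                 class_weights = class_weights, fold_plan = fold_plan),
            class = "wavelet_logistic_fit")
}

#' @export
print.wavelet_logistic_fit <- function(x, ...) {
  ci <- fold_auc_ci(x$fold_auc)
  cat(sprintf("<wavelet_logistic_fit> %d folds; mean CV AUC %.3f (95%% CI %.3f-%.3f)\n",
              length(x$fold_auc), ci$mean, ci$low, ci$high))
  invisible(x)
}

#' Tidiers for cross-validated fits
#'
#' `tidy()` returns one row per cross-validation fold (validation AUC and,
#' for the deep model, the early-stopping epoch); `glance()` returns a
#' one-row model summary (mean CV AUC with its 95% t-interval and the
#' ensemble AUC on the held-out test set).
#'
#' @param x a `wavelet_logistic_fit` or `convlstm_fit`.
#' @param ... unused.
#' @return A tibble.
#' @name actiphen-tidiers
NULL

#' @rdname actiphen-tidiers
#' @method tidy wavelet_logistic_fit
#' @export
tidy.wavelet_logistic_fit <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_auc), auc = x$fold_auc)
}

#' @rdname actiphen-tidiers
#' @method glance wavelet_logistic_fit
#' @export
glance.wavelet_logistic_fit <- function(x, ...) {
  ci <- fold_auc_ci(x$fold_auc)
  ens <- dplyr::filter(x$test_predictions, .data$fold == 0L)
  tibble::tibble(cv_auc_mean = ci$mean, cv_auc_low = ci$low,
                 cv_auc_high = ci$high,
                 test_auc = roc_auc(ens$probability, ens$label))
}
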