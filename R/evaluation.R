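#' Area under the ROC curve
#'
#' Mann-Whitney concordance: the probability that a random positive scores
#' above a random negative, with ties counting one half. Computed from
#' ranks, so it is invariant to any strictly increasing score transform.
#'
#' @param probabilities numeric scores.
#' @param labels binary vector (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.85, 0.1), c(1, 1, 0, 0))
#' @export
roc_auc <- function(probabilities, labels) {
  y <- as_label01(labels)
  stopifnot(length(probabilities) == length(y))
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(probabilities)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean and t-interval of per-fold AUCs
#'
#' @param aucs numeric vector of fold AUCs.
#' @param level confidence level (default 0.95).
#' @return List with `mean`, `low`, `high`.
#' @export
fold_auc_ci <- function(aucs, level = 0.95) {
  m <- mean(aucs)
  if (length(aucs) < 2L || sd(aucs) == 0) return(list(mean = m, low = m, high = m))
  half <- qt(1 - (1 - level) / 2, df = length(aucs) - 1L) * sd(aucs) / sqrt(length(aucs))
  list(mean = m, low = m - half, high = m + half)
}

#' Youden-optimal probability cut point
#'
#' Scans the midpoints between consecutive distinct scores (plus bounds just
#' outside the observed range) and returns the threshold maximizing
#' Youden's J = sensitivity + specificity - 1, classifying positive at
#' `probability >= cut`. Ties are broken toward the lower threshold; for
#' perfectly separated classes this returns the midpoint of the gap. If all
#' scores are identical no threshold is informative and 0.5 is returned
#' with a warning.
#'
#' @param probabilities numeric scores.
#' @param labels binary vector (both classes present).
#' @return A single threshold.
#' @export
select_cut_point <- function(probabilities, labels) {
  y <- as_label01(labels)
  u <- sort(unique(probabilities))
  if (length(u) == 1L) {
    warning("all scores identical; returning cut point 0.5", call. = FALSE)
    return(0.5)
  }
  cand <- c(u[1] - 1e-6, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1e-6)
  j <- vapply(cand, function(cut) {
    pred <- probabilities >= cut
    sens <- sum(pred & y == 1L) / sum(y == 1L)
    spec <- sum(!pred & y == 0L) / sum(y == 0L)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)] # which.max takes the first (lowest) maximizer
}

#' Confusion-matrix rates at a probability cut point
#'
#' Classifies positive at `probability >= cut` and reports sensitivity,
#' specificity, PPV and NPV (the predictive values as percentages), and
#' balanced accuracy BAC = (sensitivity + specificity) / 2. With no
#' predicted positives the PPV is undefined and reported `NA` with a
#' `ppv_undefined` flag column.
#'
#' @param probabilities numeric scores.
#' @param labels binary vector.
#' @param cut threshold in `[0, 1]`.
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv_pct`,
#'   `npv_pct`, `bac`, `ppv_undefined`.
#' @export
confusion_metrics <- function(probabilities, labels, cut) {
  y <- as_label01(labels)
  pred <- probabilities >= cut
  tp <- sum(pred & y == 1L); fp <- sum(pred & y == 0L)
  fn <- sum(!pred & y == 1L); tn <- sum(!pred & y == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp == 0L) NA_real_ else 100 * tp / (tp + fp)
  npv <- if (tn + fn == 0L) NA_real_ else 100 * tn / (tn + fn)
  tibble::tibble(sensitivity = sens, specificity = spec, ppv_pct = ppv,
                 npv_pct = npv, bac = (sens + spec) / 2,
                 ppv_undefined = tp + fp == 0L)
}

#' Population stability index between two score samples
#'
#' Bins both samples by the deciles of the reference distribution and sums
#' `(p_b - q_b) * ln(p_b / q_b)` over bins, with bin proportions floored at
#' 1e-4 so empty bins do not produce infinite terms. PSI is nonnegative,
#' zero when the binned proportions agree, and invariant to any common
#' strictly increasing transform of the scores (rank-based bins).
#'
#' @param reference scores defining the bin edges (e.g. training-fold
#'   scores).
#' @param comparison scores whose drift is measured (e.g. an evaluation
#'   set).
#' @param bins number of reference quantile bins, default 10.
#' @return Nonnegative PSI value.
#' @export
population_stability_index <- function(reference, comparison, bins = 10L) {
  if (!length(reference) || !length(comparison))
    stop("both score sets must be non-empty", call. = FALSE)
  if (length(reference) < bins || length(comparison) < bins)
    stop("fewer scores than bins", call. = FALSE)
  if (bins < 2L) stop("need at least 2 bins", call. = FALSE)
  edges <- unique(quantile(reference, probs = seq(0, 1, length.out = bins + 1L),
                           type = 7))
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  p <- tabulate(cut(reference, edges, labels = FALSE), length(edges) - 1L) /
    length(reference)
  q <- tabulate(cut(comparison, edges, labels = FALSE), length(edges) - 1L) /
    length(comparison)
  eps <- 1e-4
  p <- pmax(p, eps); q <- pmax(q, eps)
  sum((p - q) * log(p / q))
}

# psi from explicit bin proportions (used by tests and the two-bin example)
psi_from_proportions <- function(p, q, eps = 1e-4) {
  p <- pmax(p, eps); q <- pmax(q, eps)
  sum((p - q) * log(p / q))
}

#' Performance report for one fitted model
#'
#' Builds the standard evaluation rows for a cross-validated fit: per fold,
#' the cut point is chosen by Youden's J on that fold's validation
#' predictions, confusion metrics are computed at that cut, and the PSI
#' compares the fold's training-score distribution (reference) with the
#' evaluation-set scores. AUC is summarized as the mean and 95% t-interval
#' across folds. `set = "cv"` evaluates each fold model on its validation
#' fold; `set = "test"` evaluates each fold model on the held-out test set.
#' All reported rates are means across the k folds.
#'
#' @param fit a `wavelet_logistic_fit` or `convlstm_fit`.
#' @param set `"cv"` or `"test"`.
#' @param model optional model label for the report row.
#' @return One-row tibble: `model`, `set`, `auc_mean`, `auc_low`,
#'   `auc_high`, `cut_point`, `sensitivity`, `specificity`, `ppv_pct`,
#'   `npv_pct`, `bac`, `psi`.
#' @export
metrics_report <- function(fit, set = c("cv", "test"), model = class(fit)[1]) {
  set <- match.arg(set)
  k <- length(fit$fold_auc)
  rows <- vector("list", k)
  test_auc <- numeric(k)
  for (i in seq_len(k)) {
    val <- dplyr::filter(fit$cv_predictions, .data$fold == i)
    cut_i <- suppressWarnings(select_cut_point(val$probability, val$label))
    ev <- if (set == "cv") val else dplyr::filter(fit$test_predictions, .data$fold == i)
    cm <- confusion_metrics(ev$probability, ev$label, cut_i)
    cm$cut_point <- cut_i
    cm$auc <- roc_auc(ev$probability, ev$label)
    # decile bins at realistic sizes; reduced automatically for very small
    # evaluation sets so tiny smoke runs still report a PSI
    psi_bins <- min(10L, length(fit$train_scores[[i]]), nrow(ev))
    cm$psi <- if (psi_bins >= 2L) {
      population_stability_index(fit$train_scores[[i]], ev$probability,
                                 bins = psi_bins)
    } else NA_real_
    rows[[i]] <- cm
  }
  per_fold <- dplyr::bind_rows(rows)
  ci <- fold_auc_ci(per_fold$auc)
  tibble::tibble(
    model = model, set = set,
    auc_mean = ci$mean, auc_low = ci$low, auc_high = ci$high,
    cut_point = mean(per_fold$cut_point),
    sensitivity = mean(per_fold$sensitivity),
    specificity = mean(per_fold$specificity),
    ppv_pct = mean(per_fold$ppv_pct, na.rm = TRUE),
    npv_pct = mean(per_fold$npv_pct, na.rm = TRUE),
    bac = mean(per_fold$bac),
    psi = mean(per_fold$psi)
  )
}
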