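#' Savitzky-Golay smoothing of a participant-week
#'
#' Local least-squares polynomial smoothing (window default 21 minutes,
#' cubic), which denoises minute spikes while reproducing any polynomial
#' trend of degree at most `polyorder` exactly — so the morning and evening
#' ramps survive smoothing unchanged. Edge samples are handled by the
#' filter's own boundary least-squares fits (no padding), preserving the
#' polynomial-reproduction property at the week boundaries too.
#'
#' @param week numeric vector (any length > window; typically 10,080) or a
#'   participants x minutes matrix (each row smoothed independently).
#' @param window odd window width in minutes, greater than `polyorder`.
#' @param polyorder polynomial degree of the local fit.
#' @return Smoothed vector or matrix, same shape as the input.
#' @export
smooth_week <- function(week, window = 21L, polyorder = 3L) {
  if (window %% 2L != 1L) stop("`window` must be odd", call. = FALSE)
  if (window <= polyorder) stop("`window` must exceed `polyorder`", call. = FALSE)
  if (is.matrix(week)) {
    if (window >= ncol(week)) stop("`window` must be shorter than the series", call. = FALSE)
    out <- t(apply(week, 1L, signal::sgolayfilt, p = polyorder, n = window))
    dimnames(out) <- dimnames(week)
    return(out)
  }
  if (window >= length(week)) stop("`window` must be shorter than the series", call. = FALSE)
  signal::sgolayfilt(week, p = polyorder, n = window)
}

#' Reshape a 10,080-minute week into a 7 x 24 x 60 array
#'
#' Element `(d, h, m)` (1-based) equals `flat[(d-1)*1440 + (h-1)*60 + m]`:
#' a sequence of 7 daily hour-by-minute actigraphy frames.
#'
#' @param flat numeric vector of length 10,080.
#' @return A 7 x 24 x 60 array.
#' @export
reshape_week <- function(flat) {
  assert_week(flat, "flat")
  aperm(array(flat, dim = c(60L, 24L, 7L)), c(3L, 2L, 1L))
}

#' Flatten a 7 x 24 x 60 array back to the 10,080-minute week
#'
#' Exact inverse of [reshape_week()].
#' @param arr a 7 x 24 x 60 array.
#' @return Numeric vector of length 10,080.
#' @export
flatten_week <- function(arr) {
  stopifnot(is.array(arr), identical(dim(arr), c(7L, 24L, 60L)))
  as.vector(aperm(arr, c(3L, 2L, 1L)))
}

#' Reshape a cohort activity matrix into the week tensor
#'
#' @param activity participants x 10,080 matrix.
#' @return A participants x 7 x 24 x 60 array (the deep model's input).
#' @export
reshape_cohort <- function(activity) {
  stopifnot(is.matrix(activity), ncol(activity) == MINUTES_PER_WEEK)
  n <- nrow(activity)
  arr <- array(t(activity), dim = c(60L, 24L, 7L, n))
  aperm(arr, c(4L, 3L, 2L, 1L))
}

#' Per-minute z-score standardization across participants
#'
#' For each of the 10,080 minute-of-week positions, subtracts the
#' cross-participant mean and divides by the cross-participant SD
#' (population SD, divisor n, the usual z-score normalization convention).
#' Constant positions map to all-zero. By default the
#' statistics come from the full cohort; passing `train_idx` gives the
#' leakage-safe variant in which only training participants define the
#' statistics, applied to everyone.
#'
#' @param activity participants x minutes matrix (at least 2 participants).
#' @param train_idx optional integer indices of the rows used to compute the
#'   standardization statistics.
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize_per_minute <- function(activity, train_idx = NULL) {
  stopifnot(is.matrix(activity))
  if (nrow(activity) < 2L)
    stop("standardization needs at least 2 participants (SD undefined)", call. = FALSE)
  ref <- if (is.null(train_idx)) activity else activity[train_idx, , drop = FALSE]
  if (nrow(ref) < 2L) stop("need at least 2 reference participants", call. = FALSE)
  ctr <- colMeans(ref)
  centered_ref <- sweep(ref, 2L, ctr)
  scl <- sqrt(colSums(centered_ref^2) / nrow(ref))
  out <- sweep(activity, 2L, ctr)
  nz <- scl > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, scl[nz], "/")
  out[, !nz] <- 0
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Stratified train/test split with k-fold cross-validation plan
#'
#' Holds out `test_fraction` of each class (rounded per class), then assigns
#' the remaining participants, per class, to `k` cross-validation folds of
#' near-equal size. Every validation fold's positive count deviates from
#' perfect proportionality by at most one participant per class; fold
#' assignment is deterministic given the seed.
#'
#' @param labels binary vector (0/1 or logical).
#' @param test_fraction fraction held out, default 0.2.
#' @param k number of cross-validation folds, default 10.
#' @param seed integer seed.
#' @return A `fold_plan`: list with `test` (indices), `folds` (list of `k`
#'   `list(train, validation)` index pairs over the non-test participants),
#'   `k`, `seed`.
#' @export
make_fold_plan <- function(labels, test_fraction = 0.2, k = 10L, seed = 1L) {
  y <- as_label01(labels)
  n <- length(y)
  idx_pos <- which(y == 1L)
  idx_neg <- which(y == 0L)
  with_seed(seed, {
    idx_pos <- sample(idx_pos)
    idx_neg <- sample(idx_neg)
    n_test_pos <- round(test_fraction * length(idx_pos))
    n_test_neg <- round(test_fraction * length(idx_neg))
    test <- sort(c(head(idx_pos, n_test_pos), head(idx_neg, n_test_neg)))
    cv_pos <- tail(idx_pos, length(idx_pos) - n_test_pos)
    cv_neg <- tail(idx_neg, length(idx_neg) - n_test_neg)
    if (length(cv_pos) < k || length(cv_neg) < k)
      stop("too few participants per class to stratify into ", k, " folds",
           call. = FALSE)
    fold_of <- function(m) rep_len(seq_len(k), m) # shuffled upstream
    fp <- fold_of(length(cv_pos))
    fn <- fold_of(length(cv_neg))
    folds <- lapply(seq_len(k), function(i) {
      val <- sort(c(cv_pos[fp == i], cv_neg[fn == i]))
      train <- sort(c(cv_pos[fp != i], cv_neg[fn != i]))
      list(train = train, validation = val)
    })
    structure(list(test = test, folds = folds, k = as.integer(k),
                   seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' Class weights for imbalanced binary training
#'
#' Each class is weighted by the *other* class's prevalence: the negative
#' class by `n_positive / n_total` and the positive class by
#' `n_negative / n_total`, enforcing a larger loss penalty for errors on the
#' rare class. With 266 positives among 7,162 the weights are
#' 0.03714 / 0.96286.
#'
#' @param labels binary vector with both classes present.
#' @return A `class_weights` object: list with `weight_negative`,
#'   `weight_positive`.
#' @export
compute_class_weights <- function(labels) {
  y <- as_label01(labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute class weights", call. = FALSE)
  structure(list(weight_negative = n_pos / length(y),
                 weight_positive = n_neg / length(y)),
            class = "class_weights")
}

# per-observation weights from a class_weights object
sample_weights <- function(labels, cw) {
  y <- as_label01(labels)
  ifelse(y == 1L, cw$weight_positive, cw$weight_negative)
}
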