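# day-average a participants x 10080 matrix to participants x 1440
day_average <- function(mat) {
  n <- nrow(mat)
  out <- matrix(0, n, MINUTES_PER_DAY)
  for (d in seq_len(DAYS_PER_WEEK))
    out <- out + mat[, (d - 1L) * MINUTES_PER_DAY + seq_len(MINUTES_PER_DAY),
                     drop = FALSE]
  out / DAYS_PER_WEEK
}

#' Per-minute additive attributions for a ConvLSTM fit
#'
#' Integrated gradients: for each fold model, attributions are accumulated
#' along the straight path from a baseline week (the mean of a seeded
#' random background sample of that fold's training participants) to the
#' participant's week, using the trapezoid rule over `steps` interpolation
#' points. The resulting per-minute values are additive — baseline output
#' plus the summed attributions recovers the model output (checked at
#' tolerance 1e-3 in tests) — and are averaged elementwise across folds.
#' A fold whose attribution fails is excluded with a warning; at least
#' `min(5, k)` folds must survive.
#'
#' @param fit a [train_cv()] `convlstm_fit`.
#' @param tensor the standardized (n, 7, 24, 60) tensor the fit was trained
#'   on.
#' @param participants integer indices of the participants to explain
#'   (default: the held-out test set).
#' @param background_n background sample size per fold (default 100, capped
#'   at the training-fold size).
#' @param steps interpolation steps for the path integral.
#' @param seed seed for background sampling.
#' @param phq9 standardized complete PHQ-9 (required for fusion fits; held
#'   fixed at each participant's value, so attributions cover activity
#'   only).
#' @return An `attribution_map`: list with `phi` (participants x 10,080
#'   fold-averaged attributions), `base` (mean baseline output), `prob`
#'   (mean model output per participant), `participants`, `folds_used`.
#' @export
compute_attributions <- function(fit, tensor, participants = NULL,
                                 background_n = 100L, steps = 32L,
                                 seed = 1L, phq9 = NULL) {
  stopifnot(inherits(fit, "convlstm_fit"))
  if (is.null(participants)) participants <- fit$fold_plan$test
  k <- length(fit$models)
  phi_sum <- matrix(0, length(participants), MINUTES_PER_WEEK)
  base_sum <- 0; prob_sum <- numeric(length(participants))
  used <- 0L
  alphas <- seq(0, 1, length.out = steps + 1L)
  trap_w <- c(0.5, rep(1, steps - 1L), 0.5) / steps
  for (f in seq_len(k)) {
    res <- tryCatch({
      model <- fit$models[[f]]
      tr <- fit$fold_plan$folds[[f]]$train
      bg <- with_seed(seed + f,
                      sample(tr, min(background_n, length(tr))))
      base_flat <- colMeans(flatten_tensor(tensor[bg, , , , drop = FALSE]))
      base_tensor <- reshape_cohort(matrix(base_flat, 1L))
      phi_f <- matrix(0, length(participants), MINUTES_PER_WEEK)
      prob_f <- numeric(length(participants))
      base_phq <- if (fit$with_phq9) mean(phq9[bg]) else NULL
      for (j in seq_along(participants)) {
        i <- participants[j]
        x_flat <- flatten_tensor(tensor[i, , , , drop = FALSE])[1L, ]
        path <- outer(alphas, x_flat - base_flat) +
          matrix(base_flat, length(alphas), MINUTES_PER_WEEK, byrow = TRUE)
        path_tensor <- reshape_cohort(path)
        path_phq <- if (fit$with_phq9) rep(phq9[i], length(alphas)) else NULL
        g <- input_gradient(model, path_tensor, phq9 = path_phq,
                            batch_size = length(alphas))
        avg_g <- drop(crossprod(g, trap_w))
        phi_f[j, ] <- (x_flat - base_flat) * avg_g
        prob_f[j] <- predict_convlstm(model, path_tensor[length(alphas), , , ,
                                                         drop = FALSE],
                                      phq9 = path_phq[1L])
      }
      base_f <- predict_convlstm(model, base_tensor, phq9 = base_phq)
      list(phi = phi_f, base = base_f, prob = prob_f)
    }, error = function(e) {
      warning("attribution failed on fold ", f, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      phi_sum <- phi_sum + res$phi
      base_sum <- base_sum + res$base
      prob_sum <- prob_sum + res$prob
      used <- used + 1L
    }
  }
  if (used < min(5L, k))
    stop("attribution succeeded on only ", used, " fold(s); need at least ",
         min(5L, k), call. = FALSE)
  structure(list(phi = phi_sum / used, base = base_sum / used,
                 prob = prob_sum / used, participants = participants,
                 folds_used = used),
            class = "attribution_map")
}

# flatten an (n, 7, 24, 60) tensor back to n x 10080 (inverse of
# reshape_cohort)
flatten_tensor <- function(tensor) {
  n <- dim(tensor)[1]
  t(matrix(aperm(tensor, c(4L, 3L, 2L, 1L)), ncol = n))
}

#' Minute-of-day attribution summary curve
#'
#' Averages the attribution map across participants and across the 7 days
#' to 1,440 minute-of-day values, then applies a centered rolling mean of
#' width `window` minutes (edges truncated to the available support). The
#' summary is linear in the map.
#'
#' @param map an [compute_attributions()] `attribution_map`, or a numeric
#'   participants x 10,080 matrix of attributions.
#' @param window rolling window width in minutes (default 60).
#' @return Tibble: `minute_of_day` (0-1439), `attribution` (day- and
#'   participant-averaged), `attribution_smoothed`.
#' @export
summarize_attributions <- function(map, window = 60L) {
  phi <- if (inherits(map, "attribution_map")) map$phi else map
  stopifnot(is.matrix(phi), ncol(phi) == MINUTES_PER_WEEK)
  per_min <- colMeans(day_average(phi))
  tibble::tibble(minute_of_day = 0:(MINUTES_PER_DAY - 1L),
                 attribution = per_min,
                 attribution_smoothed = rolling_mean(per_min, window))
}

#' Rank correlation between movement and attribution by minute of day
#'
#' For every minute of day, the Spearman correlation across participants
#' between the (day-averaged) raw activity and the (day-averaged)
#' attribution value, followed by a centered rolling mean of width
#' `window`. Minutes where either variable has zero variance have an
#' undefined correlation, recorded as `NA` and excluded from the rolling
#' mean.
#'
#' @param activity participants x 10,080 raw activity matrix (rows aligned
#'   with the attribution map's participants).
#' @param map an `attribution_map` or participants x 10,080 matrix.
#' @param window rolling window width in minutes (default 60).
#' @return Tibble: `minute_of_day`, `rho`, `rho_smoothed`.
#' @export
attribution_activity_correlation <- function(activity, map, window = 60L) {
  phi <- if (inherits(map, "attribution_map")) map$phi else map
  stopifnot(is.matrix(activity), identical(dim(activity), dim(phi)))
  act_d <- day_average(activity)
  phi_d <- day_average(phi)
  rho <- vapply(seq_len(MINUTES_PER_DAY), function(m) {
    a <- act_d[, m]; p <- phi_d[, m]
    if (sd(a) == 0 || sd(p) == 0) return(NA_real_)
    cor(a, p, method = "spearman")
  }, numeric(1))
  tibble::tibble(minute_of_day = 0:(MINUTES_PER_DAY - 1L), rho = rho,
                 rho_smoothed = rolling_mean(rho, window))
}
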