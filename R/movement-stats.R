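#' Group mean activity with normal-approximation confidence intervals
#'
#' Each participant is summarized by the mean over their 10,080 minutes;
#' groups are summarized by the mean of participant means with a 95%
#' normal-approximation CI over participants.
#'
#' @param activity participants x 10,080 matrix.
#' @param labels binary exposure vector (1 = exposed/SSRI).
#' @param level confidence level (default 0.95).
#' @return Tibble: `group` ("exposed"/"control"), `n`, `mean`, `ci_low`,
#'   `ci_high` (counts/min).
#' @export
group_mean_activity <- function(activity, labels, level = 0.95) {
  y <- as_label01(labels)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both groups must be non-empty", call. = FALSE)
  pm <- rowMeans(activity)
  z <- qnorm(1 - (1 - level) / 2)
  one <- function(g, name) {
    v <- pm[y == g]
    se <- if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0
    tibble::tibble(group = name, n = length(v), mean = mean(v),
                   ci_low = mean(v) - z * se, ci_high = mean(v) + z * se)
  }
  dplyr::bind_rows(one(1L, "exposed"), one(0L, "control"))
}

#' Minute-of-day group activity curves
#'
#' Averages each participant's week across the 7 days to a 1,440-minute
#' curve, optionally Savitzky-Golay smooths each participant curve, and
#' summarizes per group with the cross-participant mean and pointwise 95%
#' CI. Smoothing before or after averaging is equivalent for the mean
#' (the filter is linear); it is applied per participant so the CI and the
#' slope bootstrap see the same smoothed curves.
#'
#' @param activity participants x 10,080 matrix (raw counts).
#' @param labels binary exposure vector.
#' @param smooth apply Savitzky-Golay smoothing to the daily curves?
#' @param window,polyorder smoothing parameters (see [smooth_week()]).
#' @param level confidence level.
#' @return A `group_curve` tibble: `group`, `minute_of_day`, `mean`,
#'   `ci_low`, `ci_high`; attribute `participant_curves` holds the
#'   per-group participant x 1,440 matrices used for bootstrap inference.
#' @export
group_curve <- function(activity, labels, smooth = TRUE, window = 21L,
                        polyorder = 3L, level = 0.95) {
  y <- as_label01(labels)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both groups must be non-empty", call. = FALSE)
  curves <- day_average(activity)
  if (smooth) curves <- smooth_week(curves, window, polyorder)
  z <- qnorm(1 - (1 - level) / 2)
  pc <- list(exposed = curves[y == 1L, , drop = FALSE],
             control = curves[y == 0L, , drop = FALSE])
  rows <- purrr::imap(pc, function(mat, name) {
    mu <- colMeans(mat)
    se <- if (nrow(mat) > 1L) {
      sqrt(colSums(sweep(mat, 2L, mu)^2) / (nrow(mat) - 1L)) / sqrt(nrow(mat))
    } else rep(0, ncol(mat))
    tibble::tibble(group = name, minute_of_day = 0:(MINUTES_PER_DAY - 1L),
                   mean = mu, ci_low = mu - z * se, ci_high = mu + z * se)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("group_curve", class(out))
  attr(out, "participant_curves") <- pc
  out
}

interval_minutes <- function(interval) {
  if (is.character(interval)) {
    interval <- match.arg(interval, c("morning", "evening"))
    win <- if (interval == "morning") MORNING_WINDOW else EVENING_WINDOW
  } else {
    stopifnot(is.numeric(interval), length(interval) == 2L)
    win <- as.integer(interval)
  }
  if (win[1] < 0 || win[2] > MINUTES_PER_DAY || win[2] - win[1] < 3L)
    stop("interval must lie within [0, 1440) and span at least 3 minutes",
         call. = FALSE)
  win[1]:(win[2] - 1L) # half-open [start, end)
}

ols_slope <- function(t, v) {
  tc <- t - mean(t)
  sum(tc * v) / sum(tc^2)
}

#' Best-fit activity slope over a daily interval
#'
#' Ordinary least squares slope of the group mean curve against
#' minute-of-day over the chosen interval — `"morning"` = minutes
#' [360, 540) (6-9 am), `"evening"` = [1080, 1260) (6-9 pm), or an
#' explicit half-open `c(start, end)` pair. The 95% CI comes from a seeded
#' participant-level bootstrap (resampling participants within group and
#' recomputing the group curve's slope).
#'
#' @param curve a [group_curve()] object.
#' @param interval `"morning"`, `"evening"`, or `c(start, end)` minutes.
#' @param n_boot bootstrap resamples (default 1,000).
#' @param seed bootstrap seed.
#' @param level confidence level.
#' @return Tibble: `group`, `interval`, `slope` (counts/min^2), `ci_low`,
#'   `ci_high`.
#' @export
interval_slope <- function(curve, interval = "morning", n_boot = 1000L,
                           seed = 1L, level = 0.95) {
  stopifnot(inherits(curve, "group_curve"))
  mins <- interval_minutes(interval)
  label <- if (is.character(interval)) interval else
    sprintf("[%d,%d)", interval[1], interval[2])
  pc <- attr(curve, "participant_curves")
  alpha <- (1 - level) / 2
  rows <- purrr::imap(pc, function(mat, name) {
    sub <- mat[, mins + 1L, drop = FALSE]
    est <- ols_slope(mins, colMeans(sub))
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(sub), replace = TRUE)
        ols_slope(mins, colMeans(sub[idx, , drop = FALSE]))
      }, numeric(1))
    })
    qs <- unname(quantile(boots, c(alpha, 1 - alpha)))
    tibble::tibble(group = name, interval = label, slope = est,
                   ci_low = qs[1], ci_high = qs[2])
  })
  dplyr::bind_rows(rows)
}

#' Welch two-sample t test from summary statistics
#'
#' Closed-form unequal-variance t test given group means, SDs and sizes —
#' lets printed cohort tables be tested without unit-level data.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return Tibble: `statistic`, `df`, `p_value` (two-sided).
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  se2 <- sd1^2 / n1 + sd2^2 / n2
  stat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  tibble::tibble(statistic = stat, df = df,
                 p_value = 2 * pt(-abs(stat), df))
}

#' Demographic and clinical group comparisons
#'
#' The standard cohort-description tests: chi-squared for sex and for
#' race/ethnicity (group x category contingency tables), two-sided Welch t
#' for mean age and mean PHQ-9 (observed scores only). Tests are flagged
#' significant at p < 0.05. A contingency table with a zero expected cell
#' count is rejected with the offending table attached to the error.
#'
#' @param demographics tibble with `age`, `sex`, `race`.
#' @param phq9 numeric with NA for missing.
#' @param labels binary exposure vector.
#' @return Tibble: `variable`, `test`, `statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
demographic_tests <- function(demographics, phq9, labels) {
  y <- as_label01(labels)
  grp <- factor(ifelse(y == 1L, "exposed", "control"),
                levels = c("exposed", "control"))
  chisq_row <- function(variable, values) {
    tab <- table(grp, values)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) {
      err <- simpleError(paste0("zero expected cell count for ", variable))
      err$table <- tab
      stop(err)
    }
    ct <- suppressWarnings(chisq.test(tab))
    tibble::tibble(variable = variable, test = "chi-squared",
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p_value = ct$p.value)
  }
  t_row <- function(variable, values) {
    ok <- !is.na(values)
    tt <- t.test(values[ok][y[ok] == 1L], values[ok][y[ok] == 0L])
    tibble::tibble(variable = variable, test = "Welch t",
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  }
  out <- dplyr::bind_rows(
    chisq_row("sex", demographics$sex),
    chisq_row("race", demographics$race),
    t_row("age", demographics$age),
    t_row("phq9", phq9)
  )
  dplyr::mutate(out, significant = .data$p_value < 0.05)
}
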