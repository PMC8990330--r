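#' Piecewise-linear diurnal activity profile
#'
#' Builds a 1,440-minute expected-activity profile with the canonical
#' rest-activity shape: a night trough, a linear morning ramp over 6-9 am,
#' a daytime plateau, a linear evening decline over 6-9 pm, and a final
#' taper back to the trough. The stated ramp slopes are realized exactly
#' over the morning and evening windows, so ordinary least squares on
#' either window recovers them to machine precision.
#'
#' @param plateau_level daytime plateau, in counts/min. Must be positive.
#' @param morning_slope slope of the 6-9 am ramp, counts/min^2.
#' @param evening_slope slope of the 6-9 pm decline, counts/min^2
#'   (typically negative).
#' @param trough_level night baseline, counts/min. Defaults to
#'   `plateau_level - 180 * morning_slope` (the ramp starts at the trough and
#'   reaches the plateau). Must be nonnegative.
#' @return An object of class `diurnal_profile`: a list with `values`
#'   (length 1,440, nonnegative), `morning_slope`, `evening_slope`,
#'   `trough_level`, `plateau_level`.
#' @examples
#' prof <- generate_diurnal_profile(200, morning_slope = 1, evening_slope = -0.8)
#' mean(prof$values)
#' @export
generate_diurnal_profile <- function(plateau_level,
                                     morning_slope = 0.97,
                                     evening_slope = -0.76,
                                     trough_level = NULL) {
  if (!is.numeric(plateau_level) || length(plateau_level) != 1L || plateau_level <= 0)
    stop("`plateau_level` must be a single positive number", call. = FALSE)
  if (is.null(trough_level)) trough_level <- plateau_level - 180 * morning_slope
  if (trough_level < 0)
    stop("profile would go negative: trough_level = ", signif(trough_level, 4),
         " (raise plateau_level or lower morning_slope)", call. = FALSE)
  t <- 0:(MINUTES_PER_DAY - 1L)
  lvl1260 <- plateau_level + 180 * evening_slope
  if (lvl1260 < 0)
    stop("profile would go negative at the end of the evening decline", call. = FALSE)
  values <- numeric(MINUTES_PER_DAY)
  values[t < 360] <- trough_level
  i <- t >= 360 & t < 540
  values[i] <- trough_level + morning_slope * (t[i] - 360)
  # the ramp is anchored at the trough; it meets the plateau only when
  # trough_level was left at its default
  i <- t >= 540 & t < 1080
  values[i] <- plateau_level
  i <- t >= 1080 & t < 1260
  values[i] <- plateau_level + evening_slope * (t[i] - 1080)
  i <- t >= 1260
  values[i] <- lvl1260 + (trough_level - lvl1260) / 180 * (t[i] - 1260)
  if (any(values < 0))
    stop("profile has negative expected counts; check the slope specification",
         call. = FALSE)
  structure(
    list(values = values, morning_slope = morning_slope,
         evening_slope = evening_slope, trough_level = trough_level,
         plateau_level = plateau_level),
    class = "diurnal_profile"
  )
}

# Solve for the trough so the 24-h mean of the default piecewise shape hits
# `mean_level`. Analytically, mean = trough + 112.5 * morning_slope +
# 22.5 * evening_slope (areas of the ramp/plateau/decline segments over 1440).
profile_from_mean <- function(mean_level, morning_slope, evening_slope) {
  trough <- mean_level - 112.5 * morning_slope - 22.5 * evening_slope
  if (trough < 0)
    stop("no nonnegative profile attains mean ", mean_level,
         " with these slopes", call. = FALSE)
  generate_diurnal_profile(plateau_level = trough + 180 * morning_slope,
                           morning_slope = morning_slope,
                           evening_slope = evening_slope,
                           trough_level = trough)
}

#' Overdispersed count-noise model for actigraphy minutes
#'
#' Minute counts are drawn as negative-binomial variates around the profile
#' expectation, with extra zero-inflation during night minutes (accelerometer
#' counts at rest are overdispersed and zero-heavy). The zero-inflated mean is
#' compensated (`mu / (1 - z)`) so the marginal expectation at every minute
#' equals the profile value.
#'
#' @param dispersion negative-binomial size parameter (larger = less
#'   overdispersed). `Inf` gives a noiseless draw equal to the expectation.
#' @param zero_inflation_night probability in `[0, 1)` that a night minute
#'   (minute-of-day in `[0, 360)` or `[1260, 1440)`) is forced to zero.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(dispersion = 5, zero_inflation_night = 0.3) {
  stopifnot(dispersion > 0)
  assert_prob(zero_inflation_night, "zero_inflation_night")
  if (zero_inflation_night >= 1) stop("zero_inflation_night must be < 1", call. = FALSE)
  structure(list(dispersion = dispersion,
                 zero_inflation_night = zero_inflation_night),
            class = "noise_model")
}

night_minutes_of_day <- function() {
  mod <- 0:(MINUTES_PER_DAY - 1L)
  mod < 360L | mod >= 1260L
}

# Draw `n_weeks` weeks around `profile` in one vectorized pass.
# Returns an n_weeks x 10080 matrix. Expectation at minute m is
# profile$values[(m - 1) %% 1440 + 1] for every noise model.
draw_weeks <- function(profile, noise, n_weeks) {
  mu_week <- rep(profile$values, DAYS_PER_WEEK)
  if (is.infinite(noise$dispersion) && noise$zero_inflation_night == 0) {
    return(matrix(rep(mu_week, each = n_weeks), nrow = n_weeks))
  }
  night <- rep(night_minutes_of_day(), DAYS_PER_WEEK)
  z <- ifelse(night, noise$zero_inflation_night, 0)
  mu_adj <- mu_week / (1 - z)
  total <- n_weeks * MINUTES_PER_WEEK
  mu_mat <- rep(mu_adj, each = n_weeks)
  if (is.infinite(noise$dispersion)) {
    counts <- mu_mat
  } else {
    counts <- rnbinom(total, size = noise$dispersion, mu = mu_mat)
  }
  zmat <- rep(z, each = n_weeks)
  keep <- runif(total) >= zmat
  matrix(counts * keep, nrow = n_weeks)
}

#' Simulate one participant-week of minute counts
#'
#' @param profile a [generate_diurnal_profile()] object.
#' @param noise a [noise_model()]; the default is overdispersed with night
#'   zero-inflation. Use `noise_model(Inf, 0)` for the noiseless limit, in
#'   which the week is the profile tiled 7 times exactly.
#' @param seed integer seed; the same seed gives a bitwise-identical week.
#' @return Numeric vector of 10,080 nonnegative counts.
#' @export
generate_participant_week <- function(profile, noise = noise_model(), seed = 1L) {
  if (!inherits(profile, "diurnal_profile")) stop("`profile` must be a diurnal_profile", call. = FALSE)
  if (!inherits(noise, "noise_model")) stop("`noise` must be a noise_model", call. = FALSE)
  with_seed(seed, drop(draw_weeks(profile, noise, 1L)))
}

#' Effect configuration for the synthetic cohort
#'
#' Encodes the planted exposure contrasts: a multiplicative reduction in
#' overall activity, shallower morning/evening ramps, a PHQ-9 depression-score
#' shift, and exposure-correlated demographics. Defaults reproduce the
#' contrasts observed in the 2005-2006 NHANES SSRI analysis: control 24-h mean
#' 168.8 counts/min with morning/evening slopes 0.97/-0.76 counts/min^2;
#' exposed-to-control ratios 0.71 (mean), 0.75 (morning slope), 0.51 (evening
#' slope); 3.7% exposure prevalence; PHQ-9 means 2.68 vs 2.68 + 1.58; 40.2%
#' PHQ-9 missingness.
#'
#' @param amplitude_ratio exposed/control ratio of mean activity (> 0).
#' @param morning_slope_ratio exposed/control morning-ramp slope ratio (> 0).
#' @param evening_slope_ratio exposed/control evening-decline slope ratio (> 0).
#' @param prevalence fraction exposed, in (0, 1).
#' @param phq9_shift exposed-minus-control mean PHQ-9 difference, points.
#' @param phq9_missing_rate fraction of PHQ-9 scores set missing, in `[0, 1)`.
#' @param noise a [noise_model()].
#' @param control_mean,control_morning_slope,control_evening_slope control-group
#'   diurnal profile parameters (counts/min and counts/min^2).
#' @param phq9_control_mean control-group mean PHQ-9, points.
#' @param seed integer seed for cohort generation.
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(amplitude_ratio = 0.71,
                          morning_slope_ratio = 0.75,
                          evening_slope_ratio = 0.51,
                          prevalence = 0.037,
                          phq9_shift = 1.58,
                          phq9_missing_rate = 0.402,
                          noise = noise_model(),
                          control_mean = 168.8,
                          control_morning_slope = 0.97,
                          control_evening_slope = -0.76,
                          phq9_control_mean = 2.68,
                          seed = 20220407L) {
  if (amplitude_ratio <= 0 || morning_slope_ratio <= 0 || evening_slope_ratio <= 0)
    stop("effect ratios must be positive", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) stop("`prevalence` must be in (0, 1)", call. = FALSE)
  assert_prob(phq9_missing_rate, "phq9_missing_rate")
  if (phq9_missing_rate >= 1) stop("`phq9_missing_rate` must be < 1", call. = FALSE)
  structure(
    list(amplitude_ratio = amplitude_ratio,
         morning_slope_ratio = morning_slope_ratio,
         evening_slope_ratio = evening_slope_ratio,
         prevalence = prevalence,
         phq9_shift = phq9_shift,
         phq9_missing_rate = phq9_missing_rate,
         noise = noise,
         control_mean = control_mean,
         control_morning_slope = control_morning_slope,
         control_evening_slope = control_evening_slope,
         phq9_control_mean = phq9_control_mean,
         seed = as.integer(seed)),
    class = "effect_config"
  )
}

SSRI_STEMS <- c("SERTRALINE", "ESCITALOPRAM", "FLUOXETINE", "PAROXETINE", "CITALOPRAM")
SSRI_SALTS <- c("SERTRALINE HYDROCHLORIDE", "ESCITALOPRAM OXALATE",
                "FLUOXETINE HYDROCHLORIDE", "PAROXETINE HYDROCHLORIDE",
                "CITALOPRAM HYDROBROMIDE")
NON_SSRI_MEDS <- c("IBUPROFEN", "LISINOPRIL", "METFORMIN HYDROCHLORIDE",
                   "ATORVASTATIN CALCIUM", "LEVOTHYROXINE SODIUM",
                   "AMOXICILLIN", "OMEPRAZOLE", "ALBUTEROL SULFATE")

# demographic composition per group (age mean/sd in years; P(female);
# race/ethnicity category probabilities), emulating the NHANES SSRI cohort
DEMO_PARAMS <- list(
  exposed = list(age_mean = 49.6, age_sd = 20.2, p_female = 0.699,
                 race_probs = c(Black = 0.128, White = 0.677,
                                `Mexican American` = 0.124,
                                `Other Hispanic` = 0.026, Other = 0.045)),
  control = list(age_mean = 33.1, age_sd = 22.4, p_female = 0.510,
                 race_probs = c(Black = 0.276, White = 0.388,
                                `Mexican American` = 0.260,
                                `Other Hispanic` = 0.029, Other = 0.047))
)

PHQ9_NB_SIZE <- 1.35  # matches the observed PHQ-9 variance/mean relationship

#' Generate a synthetic actigraphy cohort with planted exposure effects
#'
#' Draws exposure labels at the configured prevalence, builds group diurnal
#' profiles whose mean-activity and ramp-slope ratios equal the configured
#' effect ratios exactly in expectation, simulates each participant's
#' 10,080-minute week under the count-noise model, and attaches demographics
#' (age/sex/race shifted in the exposed group), PHQ-9 scores (truncated
#' discrete, group mean shift, missing-at-random given age and sex at exactly
#' the configured rate), and a medication table in which every exposed
#' participant carries one SSRI generic name.
#'
#' @param config an [effect_config()].
#' @param n_participants cohort size (at least 20).
#' @return An object of class `ssri_cohort`: list with `activity`
#'   (n x 10,080 matrix, rownames = participant ids), `labels` (0/1 integer),
#'   `demographics` (tibble: participant_id, age, sex, race), `phq9` (numeric
#'   with NA for missing), `medications` (tibble: participant_id,
#'   generic_name), and `config`.
#' @examples
#' coh <- generate_cohort(effect_config(prevalence = 0.1, seed = 1), 50)
#' table(coh$labels)
#' @export
generate_cohort <- function(config = effect_config(), n_participants = 2000L) {
  if (!inherits(config, "effect_config")) stop("`config` must be an effect_config", call. = FALSE)
  n <- as.integer(n_participants)
  if (n < 20L) stop("`n_participants` must be at least 20", call. = FALSE)
  if (config$prevalence * n < 2)
    stop("prevalence x n < 2: too few expected exposed participants to stratify",
         call. = FALSE)

  prof_ctrl <- profile_from_mean(config$control_mean,
                                 config$control_morning_slope,
                                 config$control_evening_slope)
  prof_exp <- profile_from_mean(config$amplitude_ratio * config$control_mean,
                                config$morning_slope_ratio * config$control_morning_slope,
                                config$evening_slope_ratio * config$control_evening_slope)

  with_seed(config$seed, {
    labels <- rbinom(n, 1L, config$prevalence)
    while (sum(labels) < 2L) labels <- rbinom(n, 1L, config$prevalence)
    n_exp <- sum(labels)
    activity <- matrix(0, n, MINUTES_PER_WEEK)
    if (n_exp > 0)
      activity[labels == 1L, ] <- draw_weeks(prof_exp, config$noise, n_exp)
    activity[labels == 0L, ] <- draw_weeks(prof_ctrl, config$noise, n - n_exp)
    ids <- sprintf("P%05d", seq_len(n))
    rownames(activity) <- ids

    grp <- ifelse(labels == 1L, "exposed", "control")
    age <- numeric(n); sex <- character(n); race <- character(n)
    for (g in c("exposed", "control")) {
      p <- DEMO_PARAMS[[g]]
      i <- grp == g
      age[i] <- pmin(pmax(rnorm(sum(i), p$age_mean, p$age_sd), 0), 95)
      sex[i] <- ifelse(runif(sum(i)) < p$p_female, "female", "male")
      race[i] <- sample(names(p$race_probs), sum(i), replace = TRUE,
                        prob = p$race_probs)
    }
    demographics <- tibble::tibble(participant_id = ids, age = age,
                                   sex = sex, race = race)

    mu_phq <- config$phq9_control_mean + config$phq9_shift * labels
    phq9 <- pmin(rnbinom(n, size = PHQ9_NB_SIZE, mu = mu_phq), 27L)
    phq9 <- as.numeric(phq9)
    n_miss <- round(config$phq9_missing_rate * n)
    if (n_miss > 0) {
      # MAR given age and sex: younger and male participants more likely missing
      w <- exp(-0.02 * age + 0.4 * (sex == "male"))
      miss_idx <- sample.int(n, n_miss, prob = w)
      phq9[miss_idx] <- NA_real_
    }

    med_rows <- vector("list", n)
    n_extra <- rbinom(n, 2L, 0.3)
    for (i in seq_len(n)) {
      meds <- character(0)
      if (labels[i] == 1L) meds <- sample(SSRI_SALTS, 1L)
      if (n_extra[i] > 0) meds <- c(meds, sample(NON_SSRI_MEDS, n_extra[i]))
      if (length(meds))
        med_rows[[i]] <- tibble::tibble(participant_id = ids[i], generic_name = meds)
    }
    medications <- dplyr::bind_rows(med_rows)

    structure(
      list(activity = activity, labels = as.integer(labels),
           demographics = demographics, phq9 = phq9,
           medications = medications, config = config),
      class = "ssri_cohort"
    )
  })
}

#' @export
print.ssri_cohort <- function(x, ...) {
  cat(sprintf("<ssri_cohort> %d participants (%d exposed, %.1f%%), %d minutes/participant\n",
              nrow(x$activity), sum(x$labels),
              100 * mean(x$labels), ncol(x$activity)))
  cat(sprintf("  PHQ-9 missing: %.1f%%; mean activity %.1f counts/min\n",
              100 * mean(is.na(x$phq9)), mean(x$activity)))
  invisible(x)
}
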