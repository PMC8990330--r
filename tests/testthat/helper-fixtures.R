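# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# small planted-effect cohort used by IO / stats tests
small_cohort <- function() {
  cached("small_cohort", function() {
    generate_cohort(effect_config(prevalence = 0.2, seed = 101L), 40L)
  })
}

# a cohort whose exposure signal is confined to minutes-of-day [480, 540):
# exposed participants get a large extra count in that window each day.
# Returns activity matrix + labels.
planted_window_cohort <- function(n = 80L, n_pos = 16L, delta = 300,
                                  window = c(480L, 540L), seed = 7L) {
  stopifnot(n_pos < n)
  withr::with_seed(seed, {
    activity <- matrix(rpois(n * 10080L, lambda = 50), n, 10080L)
    labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    mod <- (seq_len(10080L) - 1L) %% 1440L
    win_cols <- which(mod >= window[1] & mod < window[2])
    activity[labels == 1L, win_cols] <- activity[labels == 1L, win_cols] + delta
    list(activity = activity, labels = labels)
  })
}

# train a small ConvLSTM on the planted-window cohort and attribute the
# first 10 held-out participants; cached because several test files share
# it (the ~100 optimizer steps are what localize the attribution mass)
planted_window_fit <- function() {
  cached("planted_window_fit", function() {
    pw <- planted_window_cohort(n = 200L, n_pos = 40L, delta = 40, seed = 7L)
    tensor <- reshape_cohort(standardize_per_minute(smooth_week(pw$activity)))
    plan <- make_fold_plan(pw$labels, test_fraction = 0.2, k = 5L, seed = 3L)
    cfg <- conv_lstm_config(filters = c(4L, 2L), epochs = 20L, patience = 20L,
                            dropout_rate = 0.2, seed = 30L)
    fit <- train_cv(tensor, pw$labels, plan, config = cfg)
    map <- compute_attributions(fit, tensor, participants = plan$test[1:10],
                                background_n = 50L, steps = 128L, seed = 5L)
    list(fit = fit, map = map, tensor = tensor, activity = pw$activity,
         labels = pw$labels, plan = plan)
  })
}
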