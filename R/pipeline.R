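#' End-to-end run configuration
#'
#' Bundles the stage parameters for a full pipeline run: cohort source
#' (synthetic generation or ingestion of tidy CSV exchange files),
#' smoothing, splitting, both models, attribution and slope inference.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"ingest"` (read one
#'   from `paths$cohort_dir`).
#' @param effect an [effect_config()] (synthetic mode).
#' @param n_participants synthetic cohort size.
#' @param paths list with `cohort_dir` (ingest mode).
#' @param smoothing list: `window`, `polyorder`.
#' @param split list: `test_fraction`, `k`, `seed`.
#' @param model a [conv_lstm_config()].
#' @param with_phq9 also fit the PHQ-9 fusion variant?
#' @param attribution list: `participants` (count explained, from the test
#'   set), `background_n`, `steps`.
#' @param slopes list: `n_boot`.
#' @param seed global seed; stage seeds derive from it.
#' @return A `run_config` object.
#' @export
run_config <- function(mode = c("synthetic", "ingest"),
                       effect = effect_config(),
                       n_participants = 400L,
                       paths = list(),
                       smoothing = list(window = 21L, polyorder = 3L),
                       split = list(test_fraction = 0.2, k = 10L),
                       model = conv_lstm_desk_config(),
                       with_phq9 = TRUE,
                       attribution = list(participants = 20L,
                                          background_n = 100L, steps = 16L),
                       slopes = list(n_boot = 200L),
                       seed = 20220407L) {
  mode <- match.arg(mode)
  if (mode == "ingest" && is.null(paths$cohort_dir))
    stop("ingest mode requires paths$cohort_dir", call. = FALSE)
  if (mode == "ingest" && !dir.exists(paths$cohort_dir))
    stop("paths$cohort_dir does not exist: ", paths$cohort_dir, call. = FALSE)
  structure(list(mode = mode, effect = effect,
                 n_participants = as.integer(n_participants), paths = paths,
                 smoothing = smoothing, split = split, model = model,
                 with_phq9 = isTRUE(with_phq9), attribution = attribution,
                 slopes = slopes, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `effect` and
#' `model` sub-keys are passed to [effect_config()] and
#' [conv_lstm_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$effect)) args$effect <- do.call(effect_config, raw$effect)
  if (!is.null(raw$model)) args$model <- do.call(conv_lstm_config, raw$model)
  do.call(run_config, args)
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full detection pipeline
#'
#' Executes every stage against one cohort: generation or ingestion,
#' smoothing, descriptive movement statistics (group means and CIs, group
#' curves, morning/evening slopes, demographic tests), wavelet-logistic
#' baseline, per-minute standardization and tensor reshaping, ConvLSTM
#' training (activity-only and, optionally, with imputed PHQ-9 fusion),
#' temporal attribution of the activity-only model, and metric reports.
#' Artifacts are written to `out_dir`: `metrics.csv`, `group_curves.csv`,
#' `slopes.json`, `attributions.csv`, `table1.csv` and `run.log` (config
#' hash, seeds, package versions). Any stage failure aborts with a
#' stage-tagged error.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `group_means`, `curve`, `slopes`, `table1`, `baseline_fit`,
#'   `convlstm_fit`, `convlstm_phq9_fit`, `attribution`, `metrics`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                               digits = NA)
  log_line(log_con, "config sha: ",
           substr(digest_string(cfg_json), 1, 12),
           "; global seed ", config$seed)
  log_line(log_con, "R ", as.character(getRversion()),
           ", actiphen ", as.character(utils::packageVersion("actiphen")))

  stage <- function(name, expr) {
    log_line(log_con, "stage: ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (config$mode == "synthetic") {
      eff <- config$effect; eff$seed <- config$seed
      generate_cohort(eff, config$n_participants)
    } else {
      read_cohort(config$paths$cohort_dir)
    }
  })
  labels <- cohort$labels
  smoothed <- stage("smoothing",
                    smooth_week(cohort$activity, config$smoothing$window,
                                config$smoothing$polyorder))

  group_means <- stage("movement_stats", group_mean_activity(cohort$activity, labels))
  curve <- stage("group_curve",
                 group_curve(cohort$activity, labels,
                             window = config$smoothing$window,
                             polyorder = config$smoothing$polyorder))
  slopes <- stage("slopes", dplyr::bind_rows(
    interval_slope(curve, "morning", n_boot = config$slopes$n_boot,
                   seed = config$seed + 11L),
    interval_slope(curve, "evening", n_boot = config$slopes$n_boot,
                   seed = config$seed + 12L)))
  table1 <- stage("table1",
                  demographic_tests(cohort$demographics, cohort$phq9, labels))

  plan <- stage("fold_plan",
                make_fold_plan(labels, config$split$test_fraction,
                               config$split$k, seed = config$seed + 1L))
  cw <- compute_class_weights(labels[-plan$test])
  log_line(log_con, sprintf("class weights: negative %.5f, positive %.5f",
                            cw$weight_negative, cw$weight_positive))

  baseline_fit <- stage("wavelet_baseline", {
    feats <- wavelet_features(smoothed)
    fit_wavelet_logistic(feats, labels, plan, cw)
  })

  tensor <- stage("tensor", reshape_cohort(standardize_per_minute(smoothed)))
  cl_fit <- stage("convlstm", {
    cfg <- config$model; cfg$seed <- config$seed + 2L
    train_cv(tensor, labels, plan, cw, cfg)
  })
  phq_fit <- NULL
  phq_complete <- NULL
  if (config$with_phq9) {
    phq_fit <- stage("convlstm_phq9", {
      # the stage expression evaluates in this function's frame, so a plain
      # assignment is visible after the stage completes
      phq_complete <- impute_phq9(cohort$phq9, cohort$demographics)
      cfg <- config$model; cfg$seed <- config$seed + 3L
      train_cv(tensor, labels, plan, cw, cfg, phq9 = as.numeric(phq_complete))
    })
  }

  attribution <- stage("attribution", {
    sel <- head(plan$test, config$attribution$participants)
    map <- compute_attributions(cl_fit, tensor, participants = sel,
                                background_n = config$attribution$background_n,
                                steps = config$attribution$steps,
                                seed = config$seed + 4L)
    summary <- summarize_attributions(map)
    corr <- attribution_activity_correlation(
      cohort$activity[sel, , drop = FALSE], map)
    list(map = map, summary = summary, correlation = corr)
  })

  metrics <- stage("metrics", dplyr::bind_rows(
    metrics_report(baseline_fit, "cv", "wavelet_logistic"),
    metrics_report(baseline_fit, "test", "wavelet_logistic"),
    metrics_report(cl_fit, "cv", "convlstm"),
    metrics_report(cl_fit, "test", "convlstm"),
    if (!is.null(phq_fit)) metrics_report(phq_fit, "cv", "convlstm_phq9"),
    if (!is.null(phq_fit)) metrics_report(phq_fit, "test", "convlstm_phq9")))

  stage("emit", {
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"), progress = FALSE)
    curves_wide <- tidyr::pivot_wider(
      dplyr::select(tibble::as_tibble(curve), "group", "minute_of_day", "mean"),
      names_from = "group", values_from = "mean")
    readr::write_csv(curves_wide, file.path(out_dir, "group_curves.csv"),
                     progress = FALSE)
    slope_list <- purrr::pmap(slopes, function(group, interval, slope,
                                               ci_low, ci_high)
      list(slope = slope, ci_low = ci_low, ci_high = ci_high))
    names(slope_list) <- paste(slopes$group, slopes$interval, sep = "_")
    jsonlite::write_json(c(slope_list, list(seed = config$seed)),
                         file.path(out_dir, "slopes.json"),
                         auto_unbox = TRUE, digits = NA)
    att <- dplyr::left_join(attribution$summary, attribution$correlation,
                            by = "minute_of_day")
    readr::write_csv(att, file.path(out_dir, "attributions.csv"), progress = FALSE)
    readr::write_csv(table1, file.path(out_dir, "table1.csv"), progress = FALSE)
    readr::write_csv(group_means, file.path(out_dir, "group_means.csv"),
                     progress = FALSE)
  })
  log_line(log_con, "run complete")
  invisible(list(cohort = cohort, group_means = group_means, curve = curve,
                 slopes = slopes, table1 = table1,
                 baseline_fit = baseline_fit, convlstm_fit = cl_fit,
                 convlstm_phq9_fit = phq_fit, attribution = attribution,
                 metrics = metrics))
}

# small dependency-free polynomial content hash for provenance logging
digest_string <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = ""))) %% 256
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
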