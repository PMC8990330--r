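#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot minute-of-day group activity curves
#'
#' Mean activity with the pointwise 95% CI ribbon per exposure group;
#' the morning (6-9 am) and evening (6-9 pm) slope windows are shaded.
#'
#' @param object a [group_curve()] object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot group_curve
#' @export
autoplot.group_curve <- function(object, ...) {
  windows <- data.frame(xmin = c(MORNING_WINDOW[1], EVENING_WINDOW[1]),
                        xmax = c(MORNING_WINDOW[2], EVENING_WINDOW[2]))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$minute_of_day / 60,
                                       y = .data$mean,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_rect(data = windows,
                       ggplot2::aes(xmin = .data$xmin / 60,
                                    xmax = .data$xmax / 60,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, alpha = 0.08) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Hour of day", y = "Mean activity (counts/min)",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Plot an attribution summary curve
#'
#' The 60-minute rolling mean of the day- and participant-averaged
#' per-minute attributions over the day.
#'
#' @param object an [compute_attributions()] `attribution_map`.
#' @param window rolling window passed to [summarize_attributions()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot attribution_map
#' @export
autoplot.attribution_map <- function(object, window = 60L, ...) {
  s <- summarize_attributions(object, window)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$minute_of_day / 60,
                                  y = .data$attribution_smoothed)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#4477aa") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Hour of day",
                  y = sprintf("Attribution (%d-min rolling mean)", window)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold AUCs of one or more fits
#'
#' @param ... named fitted objects (`wavelet_logistic_fit` /
#'   `convlstm_fit`).
#' @return A ggplot object.
#' @export
plot_fold_auc <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, function(f) class(f)[1], character(1))
  df <- dplyr::bind_rows(purrr::imap(fits, function(f, nm)
    tibble::tibble(model = nm, fold = seq_along(f$fold_auc), auc = f$fold_auc)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "Validation AUC") +
    ggplot2::theme_minimal()
}
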