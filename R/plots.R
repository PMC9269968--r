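#' Plot a COP trajectory
#'
#' Stabilogram of one window or trial: the COP path with the mean COP marked,
#' ML on the horizontal axis, CC on the vertical (the usual top-view
#' convention, head up).
#'
#' @param segment COP tibble (columns `ml_mm`, `cc_mm`).
#' @return A ggplot object.
#' @export
plot_cop_path <- function(segment) {
  m <- mean_cop(segment)
  ggplot2::ggplot(segment, ggplot2::aes(x = .data$ml_mm, y = .data$cc_mm)) +
    ggplot2::geom_path(colour = "steelblue", alpha = 0.7) +
    ggplot2::geom_point(size = 0.6, colour = "steelblue") +
    ggplot2::annotate("point", x = m[["ml"]], y = m[["cc"]], colour = "red",
                      size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML (mm)", y = "CC (mm)", title = "COP trajectory")
}

#' Compare a sway metric between groups
#'
#' Boxplot with jittered points of one metric by age group, on a log scale
#' (sway measures are right-skewed).
#'
#' @param metrics Per-dog metrics tibble joined with a `group` column, or the
#'   output of [dog_metrics()] plus `dogs` supplied separately.
#' @param metric Metric column name (see [sway_metric_names()]).
#' @param dogs Optional cohort tibble to supply `group` via `dog_id`.
#' @return A ggplot object.
#' @export
plot_metric_by_group <- function(metrics, metric = "rms_ov", dogs = NULL) {
  if (!is.null(dogs)) {
    metrics <- dplyr::inner_join(metrics, dogs[c("dog_id", "group")], by = "dog_id")
  }
  stopifnot("group" %in% names(metrics), metric %in% names(metrics))
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$group, y = .data[[metric]],
                               colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "group", y = metric) +
    ggplot2::theme(legend.position = "none")
}

#' Plot the reliability table
#'
#' ICC point estimates with 95% confidence intervals per metric, with the
#' conventional reliability bands (0.5, 0.75, 0.9) marked.
#'
#' @param reliability The `reliability` tibble of [analyze_cohort()].
#' @return A ggplot object.
#' @export
plot_reliability <- function(reliability) {
  reliability$metric <- factor(reliability$metric,
                               levels = rev(sway_metric_names()))
  ggplot2::ggplot(reliability,
                  ggplot2::aes(x = .data$icc, y = .data$metric)) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9), linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.25) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ICC(2,k)", y = NULL, title = "Trial-to-trial reliability")
}
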