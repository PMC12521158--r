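# ggplot2 visualizations for the main result types.

#' @describeIn metrics_for_subject Plot a subject's global metric curves
#'   across the sparsity sweep.
#' @param object A `metric_curves` object.
#' @export
autoplot.metric_curves <- function(object, ...) {
  d <- dplyr::filter(object$curves, .data$scope == "global")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "sparsity threshold", y = "metric value",
                  title = sprintf("Global metric curves: %s", object$subject_id)) +
    ggplot2::theme_minimal()
}

#' Group-mean metric curves across the sparsity sweep
#'
#' Plots, for each global metric, the per-group mean curve with a +/- 1 SD
#' ribbon — the usual visualization accompanying AUC-based group
#' comparisons.
#'
#' @param curves_tbl Long table of per-subject curves (columns
#'   `subject_id`, `metric`, `scope`, `node`, `threshold`, `value`), e.g.
#'   bound rows of `metrics_for_subject()$curves`.
#' @param clinical Clinical table with `subject_id` and `group`.
#' @param metrics Which global metrics to show (default all).
#' @return A ggplot object.
#' @export
plot_group_curves <- function(curves_tbl, clinical, metrics = NULL) {
  d <- curves_tbl |>
    dplyr::filter(.data$scope == "global") |>
    dplyr::left_join(clinical[, c("subject_id", "group")], by = "subject_id")
  if (!is.null(metrics)) d <- dplyr::filter(d, .data$metric %in% metrics)
  d <- d |>
    dplyr::group_by(.data$group, .data$metric, .data$threshold) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$mean,
                                  colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "sparsity threshold", y = "group mean +/- SD") +
    ggplot2::theme_minimal()
}

#' @describeIn roc_analysis Plot the ROC curve with the chance diagonal and
#'   the Youden-optimal operating point.
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @export
autoplot.roc_curve <- function(object, ...) {
  d <- object$curve
  op <- object$operating_point
  ggplot2::ggplot(d, ggplot2::aes(x = 1 - .data$specificity,
                                  y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 1 - op$specificity, y = op$sensitivity,
                      colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %0.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Degree or link-weight distributions by group
#'
#' Frequency polygons of pooled per-group distributions, the companion
#' plot to [compare_distributions()].
#'
#' @param values_by_group Named list of numeric vectors (one per group).
#' @param bins Number of bins.
#' @param xlab Axis label.
#' @return A ggplot object.
#' @export
plot_distributions <- function(values_by_group, bins = 30,
                               xlab = "value") {
  d <- purrr::imap_dfr(values_by_group, function(v, g) {
    tibble::tibble(group = g, value = v)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, colour = .data$group)) +
    ggplot2::geom_freqpoly(bins = bins,
                           ggplot2::aes(y = ggplot2::after_stat(.data$density))) +
    ggplot2::labs(x = xlab, y = "density") +
    ggplot2::theme_minimal()
}

#' @describeIn forward_lr_logistic Forest plot of odds ratios with Wald 95%
#'   confidence intervals (log scale).
#' @param object A `forward_lr_fit`.
#' @export
autoplot.forward_lr_fit <- function(object, ...) {
  d <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_ci_low,
                                         xmax = .data$or_ci_high),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
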