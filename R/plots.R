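#' Plot an ROC curve
#'
#' @param object an `asl_roc` from [roc_auc()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.asl_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the scan-number reduction curve
#'
#' Balanced accuracy, sensitivity and specificity as a function of the number
#' of ASL scans averaged per session.
#'
#' @param object an `asl_scan_curve` from [scan_reduction_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.asl_scan_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("side", "n_scans", "sensitivity",
                                "specificity", "balanced_accuracy")],
    cols = c("sensitivity", "specificity", "balanced_accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_scans, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~side) +
    ggplot2::scale_x_continuous(breaks = sort(unique(long$n_scans))) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "ASL scans averaged per session", y = "Rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-subject predictive probability strip plot
#'
#' Mirrors the classical per-subject display: the probability that each scan
#' came from the comparison (presurgical / follow-up) state, one row per
#' subject, squares for postsurgical and diamonds for comparison samples;
#' points on the correct side of the 0.5 line are correctly classified.
#'
#' @param preds prediction tibble from [classify_loocv()].
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_probability_strip <- function(preds, ...) {
  df <- dplyr::mutate(
    preds,
    p_comparison = 1 - .data$prob,
    state = ifelse(.data$truth == 1, "postsurgery", "comparison")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_comparison, y = .data$subject_id,
                                   colour = .data$state, shape = .data$state)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_point(size = 2.4, alpha = 0.85) +
    ggplot2::scale_shape_manual(values = c(postsurgery = 15, comparison = 18)) +
    ggplot2::scale_colour_manual(values = c(postsurgery = "#c0392b",
                                            comparison = "#2e6da4")) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "Predictive probability of the comparison state",
                  y = NULL, colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Mid-slice heatmap of a g-map
#'
#' @param gmap an `asl_gmap`.
#' @param k axial slice index (default: middle slice).
#' @return a ggplot.
#' @export
plot_gmap_slice <- function(gmap, k = NULL) {
  if (is.null(k)) k <- ceiling(gmap$grid_shape[3] / 2)
  df <- tidy.asl_gmap(gmap) |> dplyr::filter(.data$k == !!k)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$g)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey95",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("g-map, axial slice %d (%s)",
                                  k, gmap$sign_convention),
                  x = NULL, y = NULL, fill = "g") +
    ggplot2::theme_minimal()
}
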