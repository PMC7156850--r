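# ggplot2 front-ends for the result objects.

#' Plot a reliability diagram
#'
#' Bin confidence against empirical foreground fraction, with the identity
#' line as perfect calibration and bar heights showing the voxel counts.
#'
#' @param object a `uq_reliability`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot uq_reliability
#' @export
autoplot.uq_reliability <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$occupied, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, y = .data$accuracy)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_col(ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                   y = .data$count / max(.data$count) * 0.25),
                      width = 1 / length(object$counts), alpha = 0.25,
                      fill = "steelblue") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "confidence (foreground probability)",
      y = "empirical foreground fraction",
      title = sprintf("Reliability (%s scope%s), ECE = %.3f",
                      object$scope,
                      if (is.na(object$region)) "" else
                        paste0(", ", object$region),
                      expected_calibration_error(object))) +
    ggplot2::theme_minimal()
}

#' Plot a failure-detection ROC curve
#'
#' @param object a `uq_failure_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot uq_failure_result
#' @export
autoplot.uq_failure_result <- function(object, ...) {
  if (is.null(object$roc)) stop("no ROC available (single-class cohort)",
                                call. = FALSE)
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s / %s: AUC %.3f, Youden accuracy %.3f",
                                  object$family, object$region,
                                  object$auc_roc, object$youden_accuracy)) +
    ggplot2::theme_minimal()
}

#' Plot a U-E threshold sweep
#'
#' Mean validation U-E against threshold, with the selected threshold
#' marked.
#'
#' @param x a `uq_threshold`.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_threshold_sweep <- function(x, ...) {
  stopifnot(inherits(x, "uq_threshold"))
  ggplot2::ggplot(x$sweep, ggplot2::aes(x = .data$threshold,
                                        y = .data$mean_ue)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = x$threshold, linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::labs(x = "uncertainty threshold", y = "mean validation U-E",
                  title = sprintf("%s / %s: selected threshold %.2f",
                                  x$method_id, x$region, x$threshold)) +
    ggplot2::theme_minimal()
}
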