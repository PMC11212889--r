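#' Plot detection metrics across the IoU threshold sweep
#'
#' @param object an `iou_sweep` tibble from [sweep_thresholds()].
#' @param ... unused.
#' @return A ggplot: F1, precision, recall and detection accuracy versus
#'   IoU threshold.
#' @method autoplot iou_sweep
#' @export
autoplot.iou_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object, c("f1", "precision", "recall", "detection_accuracy"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iou_threshold,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "IoU threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Height distribution by hair-cell row
#'
#' @param heights tibble from [measure_heights()].
#' @param rows row assignment from [row_assign()].
#' @return A ggplot violin/jitter plot of bundle height by row.
#' @export
plot_heights_by_row <- function(heights, rows) {
  df <- dplyr::left_join(heights, rows[c("bundle_id", "row")],
                         by = "bundle_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$height_um)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, size = 0.8) +
    ggplot2::labs(x = NULL, y = "bundle height (µm)") +
    ggplot2::theme_minimal()
}

#' Observer-agreement scatter plot
#'
#' @param x,y paired measurement vectors.
#' @param labels axis labels.
#' @return A ggplot scatter with the identity line.
#' @export
plot_agreement <- function(x, y, labels = c("method A", "method B")) {
  df <- tibble::tibble(x = x, y = y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = labels[1], y = labels[2]) +
    ggplot2::theme_minimal()
}
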