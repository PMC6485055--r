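#' Plot a face image with its landmarks
#'
#' @param image grayscale matrix
#' @param landmarks optional landmark or salient-point tibble to overlay
#' @return a ggplot object
#' @export
plot_face <- function(image, landmarks = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(image)), x = seq_len(ncol(image)))
  df$value <- as.vector(t(image))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(landmarks)) {
    p <- p + ggplot2::geom_point(data = landmarks, colour = "red", size = 0.6)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods for palsymetry result objects
#'
#' `palsy_roc`: the ROC curve with the chance diagonal and the AUC in the
#' subtitle. `cv_result`: per-parameter averaged sensitivity/specificity
#' with the selected regularization highlighted. `iris_segment`: the visible
#' iris mask. `eval_metrics`: per-stage bars.
#'
#' @param object the result object
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.palsy_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false-positive rate (1 - specificity)",
                  y = "true-positive rate (sensitivity)",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.palsy_roc
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$averages, c("sensitivity", "specificity"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_lambda, linetype = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "regularization parameter (lambda)",
                  y = "cross-validated average") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.palsy_roc
#' @export
autoplot.iris_segment <- function(object, ...) {
  m <- object$visible_mask
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$visible <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$visible)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(subtitle = sprintf("visible iris area: %d px", object$area)) +
    ggplot2::theme_void()
}

#' @rdname autoplot.palsy_roc
#' @export
autoplot.eval_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(object[, c("stage", "sensitivity", "specificity")],
                            c("sensitivity", "specificity"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
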