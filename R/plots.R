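#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_boxplot geom_line
#'   geom_point geom_raster facet_wrap labs scale_fill_viridis_c
#'   scale_y_continuous position_dodge theme_minimal scale_fill_brewer
#'   geom_errorbar
#' @export
ggplot2::autoplot

#' Plot an evaluation report
#'
#' Bar chart of precision/recall/F1 per accuracy level, with error bars
#' showing the across-sequence standard deviation.
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(c("precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    mutate(sd = dplyr::case_when(metric == "precision" ~ .data$precision_sd,
                                 metric == "recall" ~ .data$recall_sd,
                                 TRUE ~ .data$f1_sd),
           level = factor(.data$level, levels = object$summary$level))
  ggplot(df, aes(x = .data$level, y = .data$value, fill = .data$metric)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    geom_errorbar(aes(ymin = .data$value - .data$sd,
                      ymax = pmin(.data$value + .data$sd, 1)),
                  position = position_dodge(0.8), width = 0.2, na.rm = TRUE) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "accuracy level", y = NULL, fill = NULL,
         title = "Sensor detection performance by accuracy level") +
    theme_minimal()
}

#' Plot a noise-robustness study
#'
#' Grouped F1 bars per noise level and accuracy level.
#'
#' @param object a `noise_study`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.noise_study <- function(object, ...) {
  df <- object$summary |>
    mutate(noise_level = factor(.data$noise_level, levels = object$levels),
           level = factor(.data$level,
                          levels = unique(object$summary$level)))
  ggplot(df, aes(x = .data$noise_level, y = .data$f1, fill = .data$level)) +
    geom_col(position = position_dodge(0.8), width = 0.7) +
    scale_y_continuous(limits = c(0, 1)) +
    scale_fill_brewer(palette = "Blues") +
    labs(x = "noise level", y = "F1-score", fill = "accuracy",
         title = "Detection robustness under added Gaussian noise") +
    theme_minimal()
}

#' Box plots of detection distance by sensor index
#'
#' The per-sensor error profile along the catheter, top to bottom:
#' distances of matched detections to their true sensor, grouped by the
#' truth sensor index.
#'
#' @param report an `eval_report`.
#' @return A ggplot.
#' @export
plot_distance_by_index <- function(report) {
  d <- distance_by_sensor_index(report)$distances
  ggplot(d, aes(x = factor(.data$sensor_index), y = .data$distance)) +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = "sensor index (top to bottom)", y = "distance to truth [px]",
         title = "Detection error along the catheter") +
    theme_minimal()
}

#' Quick-look plot of a frame with detections
#'
#' Renders a grayscale frame with the detected catheter line and sensor
#' centers (inferred sensors marked by open symbols).
#'
#' @param image grayscale matrix.
#' @param line optional `catheter_line`.
#' @param sensors optional `sensor_set`.
#' @return A ggplot.
#' @export
plot_frame <- function(image, line = NULL, sensors = NULL) {
  df <- tibble(row = rep(seq_len(nrow(image)), ncol(image)),
               col = rep(seq_len(ncol(image)), each = nrow(image)),
               value = as.vector(image))
  p <- ggplot(df, aes(x = .data$col, y = .data$row)) +
    geom_raster(aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() + theme_minimal() + labs(x = NULL, y = NULL)
  if (!is.null(line))
    p <- p + geom_line(data = as_tibble(line), ggplot2::aes(group = 1),
                       color = "cyan", linewidth = 0.3)
  if (!is.null(sensors) && nrow(sensors) > 0)
    p <- p + geom_point(data = as_tibble(sensors),
                        aes(shape = .data$inferred), color = "red", size = 1.5) +
      ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                  guide = "none")
  p
}
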