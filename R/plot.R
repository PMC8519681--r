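#' Plot a depth-dose curve
#'
#' @param object A `pdd_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pdd_curve <- function(object, ...) {
  lbl <- attr(object, "label")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_mm,
                                       y = .data$dose_percent)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Depth in water (mm)", y = "Relative dose (%)",
                  title = lbl) +
    ggplot2::theme_minimal()
}

#' Plot a fitted primary-tail model over its data
#'
#' Measured points with the fitted model drawn on a fine grid.
#'
#' @param object A `pdd_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pdd_fit <- function(object, ...) {
  dense <- seq(min(object$data$depth_mm), max(object$data$depth_mm),
               length.out = 400)
  model <- pdd_model(dense, object$params, normalize = TRUE)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$depth_mm,
                                            y = .data$dose_percent)) +
    ggplot2::geom_line(data = model, colour = "steelblue") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "Depth in water (mm)", y = "Relative dose (%)",
                  subtitle = sprintf("rms deviation %.2f%% (%s tail)",
                                     object$rms_deviation,
                                     object$params$tail_form)) +
    ggplot2::theme_minimal()
}
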