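#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a slice of an image volume
#'
#' @param object an [image_volume()].
#' @param slice slice index (default: middle slice).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.image_volume <- function(object, slice = NULL, ...) {
  d <- dim(object$data)
  s <- slice %||% ceiling(d[3] / 2)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$hu <- as.vector(object$data[, , s])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (slice %d)", object$modality, s),
                  fill = "HU") +
    ggplot2::theme_minimal()
}

#' Metric distributions per model and route
#'
#' @param object an `smv_report`.
#' @param metric which metric column to plot.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.smv_report <- function(object, metric = "dsc", ...) {
  df <- object$per_case
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data[[metric]],
                                   colour = .data$model)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::facet_wrap(~route) +
    ggplot2::labs(y = metric, x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Training loss trace of a translator
#'
#' @param translator a `trained_translator`.
#' @return a ggplot of the per-step loss components.
#' @export
plot_loss_trace <- function(translator) {
  tr <- translator$trace
  long <- tidyr::pivot_longer(tr, -dplyr::all_of(c("step", "epoch")),
                              names_to = "component", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training step", y = "loss") +
    ggplot2::theme_minimal()
}
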