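#' Plot a composition report
#'
#' Bar chart of per-class volume fractions, annotated with the mean
#' calibrated intensity of each class.
#'
#' @param object a `vh_composition` from [quantify_composition()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.vh_composition <- function(object, ...) {
  df <- as.data.frame(object)
  df$class <- factor(df$class, levels = df$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$vol_pct)) +
    ggplot2::geom_col(fill = "firebrick", alpha = 0.8) +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(is.na(.data$mean_intensity), "",
                                  sprintf("MI %.0f", .data$mean_intensity))),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "volume fraction (%)",
                  title = "Clot composition") +
    ggplot2::theme_minimal()
}

#' Plot one z-slice of a volume (optionally with segmentation contours)
#'
#' @param volume a [vh_volume()].
#' @param z slice index (default: middle slice).
#' @param labels optional [vh_labels()] overlaid as filled contours.
#' @return a ggplot.
#' @export
plot_slice <- function(volume, z = NULL, labels = NULL) {
  stopifnot_volume(volume)
  d <- dim(volume$data)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- volume$data[, , z]
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.numeric(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = volume$semantics) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("slice z = %d (%s)", z, volume$semantics)) +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    lf <- df
    lf$lab <- as.numeric(labels$labels[, , z])
    lf <- lf[lf$lab > 0 & lf$lab <= nrow(labels$schema), ]
    lf$class <- factor(labels$schema$class[lf$lab], levels = labels$schema$class)
    p <- p + ggplot2::geom_tile(data = lf,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$class),
                                fill = NA, inherit.aes = FALSE,
                                linewidth = 0.1, alpha = 0.4)
  }
  p
}
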