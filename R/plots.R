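#' Plot per-ROI traces as a stacked raster-free line panel
#'
#' @param x a [trace_matrix()] or [dff_matrix()].
#' @param offset vertical offset between successive ROI traces (default:
#'   the 95th percentile of the absolute values).
#' @return A ggplot object.
#' @export
plot_traces <- function(x, offset = NULL) {
  require_ggplot()
  df <- as_trace_tibble(x)
  if (is.null(offset))
    offset <- 2 * quantile(abs(df$value), 0.95, na.rm = TRUE, names = FALSE)
  df$y <- df$value + offset * (match(df$roi_id, unique(df$roi_id)) - 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$y,
                                   group = .data$roi_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "ROI (offset traces)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot a motif correlation map
#'
#' Heatmap of motif-by-frame correlations; sub-threshold (zeroed) columns
#' show as background.
#'
#' @param cmap a `corr_map` from [motif_correlation_map()].
#' @return A ggplot object.
#' @export
plot_correlation_map <- function(cmap) {
  require_ggplot()
  ca <- cmap$Ca
  df <- expand.grid(motif = seq_len(nrow(ca)), frame = seq_len(ncol(ca)))
  df$corr <- as.vector(ca)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$motif,
                                   fill = .data$corr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = "frame (10 Hz)", y = "motif", fill = "r") +
    ggplot2::theme_minimal()
}

#' Plot a pairwise correlation matrix
#'
#' @param sync a `synchrony_result`.
#' @param thresholded plot the surrogate-thresholded matrix (default) or
#'   the raw one.
#' @return A ggplot object.
#' @export
plot_corr_matrix <- function(sync, thresholded = TRUE) {
  require_ggplot()
  m <- if (thresholded) sync$corr_matrix else sync$raw_corr
  df <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$corr <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$corr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "ROI", y = "ROI", fill = "r") +
    ggplot2::theme_minimal()
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}
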