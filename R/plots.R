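#' Overlay KDE frequency curves per group
#'
#' The flow-cytometry-style frequency plot: one smoothed intensity curve per
#' group, faceted by modality when both are present.
#'
#' @param events An event table (see [event_table()]).
#' @param n_grid,bandwidth Passed to [kde_curve()].
#' @return A ggplot object.
#' @export
plot_kde_overlay <- function(events, n_grid = 512L, bandwidth = NULL) {
  curves <- events |>
    dplyr::group_by(.data$modality, .data$group) |>
    dplyr::reframe(kde_curve(.data$intensity_8bit, n_grid, bandwidth))
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$grid, y = .data$density,
                                    colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "intensity (8-bit)", y = "density",
                  colour = "group") +
    ggplot2::theme_minimal()
  if (length(unique(curves$modality)) > 1L) {
    p <- p + ggplot2::facet_wrap(~modality, scales = "free")
  }
  p
}

#' Bar chart of relative histogram-characteristic changes
#'
#' One bar per metric x group, side by side for the two modalities — the
#' machine-readable twin of a histogram-characteristics comparison panel.
#'
#' @param rel Tibble from [relative_changes()] (may pool both modalities).
#' @return A ggplot object.
#' @export
plot_relative_changes <- function(rel) {
  ggplot2::ggplot(rel,
                  ggplot2::aes(x = .data$metric, y = .data$rel_change_pct,
                               fill = .data$modality)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "relative change vs control (%)",
                  fill = "modality") +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot cyto_concordance
autoplot.cyto_concordance <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("rel_change_imaging_pct", "rel_change_flow_pct"),
    names_to = "modality", values_to = "rel_change_pct")
  long$modality <- sub("^rel_change_(.*)_pct$", "\\1", long$modality)
  plot_relative_changes(long)
}

#' @export
#' @method autoplot cyto_segmentation
autoplot.cyto_segmentation <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells,
                  ggplot2::aes(x = .data$equivalent_diameter_um,
                               y = .data$mean_intensity_8bit)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "equivalent diameter (um)",
                  y = "whole-cell mean intensity (8-bit)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
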