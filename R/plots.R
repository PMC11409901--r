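#' Scatter plot of localizations
#'
#' Lateral (x-y) scatter of a localization table, optionally coloured by
#' cluster assignment, channel or photon count. Intended for quick QC of
#' simulated or filtered data, not publication rendering.
#'
#' @param locs A localization tibble.
#' @param color_by `"cluster"`, `"channel"` or `"photon_count"` (any that is
#'   present); `NULL` for plain points.
#' @param point_size Point size.
#' @return A ggplot object.
#' @export
plot_localizations <- function(locs, color_by = NULL, point_size = 0.3) {
  locs <- as_tibble(locs)
  p <- ggplot2::ggplot(locs, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(color_by) && color_by %in% names(locs)) {
    if (color_by == "cluster") {
      locs$.col <- factor(ifelse(locs$cluster > 0, locs$cluster, NA))
      p <- ggplot2::ggplot(locs, ggplot2::aes(x = .data$x, y = .data$y,
                                              colour = .data$.col)) +
        ggplot2::scale_colour_discrete(na.value = "grey80", guide = "none")
    } else {
      p <- ggplot2::ggplot(locs, ggplot2::aes(x = .data$x, y = .data$y,
                                              colour = .data[[color_by]]))
    }
  }
  p +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a maPC sweep
#'
#' Visualises how the FOCAL-PC photon-count gate sharpens detection: mean
#' cluster radius, mean platform density, mean localizations per cluster and
#' the clustered percentage as functions of maPC.
#'
#' @param sweep A tibble from [sweep_mapc()].
#' @return A ggplot object (facetted line plot).
#' @export
plot_mapc_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    sweep,
    cols = c("mean_radius", "mean_density_platform",
             "mean_locs_per_cluster", "pct_locs_clustered"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ma_pc, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "maPC (photons)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histograms of per-cluster metrics
#'
#' Distribution of cluster radii and platform densities from a
#' [summarize_clusters()] table, the standard way aggregate populations are
#' presented.
#'
#' @param records A per-cluster metrics tibble.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_cluster_metrics <- function(records, bins = 30) {
  long <- tidyr::pivot_longer(
    records,
    cols = c("radius", "density_platform"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "clusters") +
    ggplot2::theme_minimal()
}
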