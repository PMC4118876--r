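#' Plot a per-frame time series table
#'
#' Lines for every numeric column of a tidy time-series table (as produced
#' by [domain_metrics()], [rmsd_series()], [sulfur_distance_series()] or
#' read back by [read_timeseries()]).
#'
#' @param table A tibble with a `frame` column and numeric value columns.
#' @param ylab Y-axis label (values are Angstrom or degrees depending on
#'   the metric).
#' @return A ggplot object.
#' @export
plot_timeseries <- function(table, ylab = "value") {
  long <- tidyr::pivot_longer(table, -"frame", names_to = "series",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot closest-distance time courses of bridge pairs
#'
#' One panel per residue pair with the bridge threshold drawn as a dashed
#' line.
#'
#' @param series Output of [salt_bridge_series()].
#' @param threshold Cutoff line to draw (Angstrom).
#' @return A ggplot object.
#' @export
plot_contact_series <- function(series, threshold = 3.0) {
  series <- mutate(series,
                   pair = paste0(.data$res_pos, "-", .data$res_neg))
  ggplot2::ggplot(series, ggplot2::aes(x = .data$frame,
                                       y = .data$min_distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "frame", y = "closest distance (Å)") +
    ggplot2::theme_minimal()
}

#' @rdname compactness_report
#' @param object A `compactness_report`.
#' @export
autoplot.compactness_report <- function(object, ...) {
  dist_cols <- grep("^(dist_|sulfur)", names(object$series), value = TRUE)
  plot_timeseries(object$series[, c("frame", dist_cols)],
                  ylab = "distance (Å)")
}
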