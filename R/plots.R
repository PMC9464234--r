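# ggplot2 quick-look figures for the main result types.

#' Plot a composite curve
#'
#' Median anomaly with the 95% band, age increasing to the left as usual
#' for Holocene time series.
#'
#' @param object A `composite_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.composite_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center / 1000)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95,
                                      ymax = .data$upper95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue4") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (ka BP)", y = "Temperature anomaly (°C)")
}

#' Plot a reconstruction series
#'
#' Estimates with sample-specific error bars, one panel per climate
#' variable.
#'
#' @param object A `recon_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.recon_series <- function(object, ...) {
  d <- as_tibble(object) %>% filter(is.finite(.data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age / 1000, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$sample_error,
                                      ymax = .data$estimate + .data$sample_error),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (ka BP)", y = "Temperature (°C)")
}

#' Plot an EOF correlation map
#'
#' Per-unit Pearson correlation with PC1; when site coordinates are
#' supplied the units are placed on a lat/lon map.
#'
#' @param object An `eof_result`.
#' @param sites Optional tibble (`site_id`, `lat`, `lon`) matched to the
#'   unit names.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eof_result <- function(object, sites = NULL, ...) {
  cm <- object$correlation_map
  if (!is.null(sites)) {
    cm <- left_join(cm, sites, by = c(unit = "site_id"))
    return(
      ggplot2::ggplot(cm, ggplot2::aes(.data$lon, .data$lat,
                                       colour = .data$r)) +
        ggplot2::geom_point(size = 2.5) +
        ggplot2::scale_colour_gradient2(limits = c(-1, 1)) +
        ggplot2::labs(x = "Longitude", y = "Latitude",
                      colour = "r(series, PC1)")
    )
  }
  ggplot2::ggplot(cm, ggplot2::aes(x = stats::reorder(.data$unit, .data$r),
                                   y = .data$r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "r(series, PC1)")
}
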