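# ggplot2 visualisations for the main result types.

#' Plot an NSD segmentation
#'
#' Daily NSD time series per individual, coloured by decoded latent state
#' (1 = summer encampment, 2 = winter encampment, 3 = transit).
#'
#' @param object An `nsd_states` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nsd_states <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$date, .data$nsd_km2 / 1e6,
                                   colour = factor(.data$state))) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~id, scales = "free_x") +
    ggplot2::labs(x = NULL, y = expression(NSD ~ (10^6 ~ km^2)),
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot a behavioural clustering
#'
#' Hourly records in the depth - speed plane, coloured by cluster and shaped
#' by assigned mode.
#'
#' @param object A `dive_clusters` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dive_clusters <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$speed_kmh, .data$depth_m,
                                   colour = factor(.data$cluster),
                                   shape = .data$mode)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "travel speed (km/h)", y = "mean max depth (m)",
                  colour = "cluster", shape = "mode") +
    ggplot2::theme_minimal()
}

#' Plot winter-range occupancy
#'
#' @param object Occupancy tibble from [winter_range()].
#' @param ... Unused.
#' @return A ggplot tile map of days per 1-degree cell.
#' @export
plot_occupancy <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lon_bin, .data$lat_bin,
                                       fill = .data$days)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "days") +
    ggplot2::theme_minimal()
}

#' Plot fitted habitat smooths
#'
#' Centred smooth effects (logit scale) of each environmental term over the
#' central 90% of its observed range.
#'
#' @param object A `habitat_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.habitat_fit <- function(object, ...) {
  df <- purrr::map_dfr(object$env_terms, function(tm) {
    dplyr::mutate(smooth_estimate(object, tm), term = tm)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$effect)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "red") +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "smooth effect (logit)") +
    ggplot2::theme_minimal()
}

#' Plot seasonal orientation-class proportions
#'
#' @param object Output of [proportion_table()].
#' @param ... Unused.
#' @return A ggplot bar chart per stage and season.
#' @export
plot_orientation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$season, .data$mean_pct,
                                       fill = .data$klass)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_pct - .data$sd_pct,
                   ymax = .data$mean_pct + .data$sd_pct),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::facet_grid(.data$medium ~ .data$stage) +
    ggplot2::labs(x = NULL, y = "% of 12-h segments", fill = NULL) +
    ggplot2::theme_minimal()
}
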