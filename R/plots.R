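#' Plot a year of daily ice fractions with its transition dates
#'
#' @param series Tibble `year`, `doy`, `fraction` (one or more years).
#' @param metrics Optional [season_metrics()] tibble; transition dates are
#'   drawn as vertical lines when supplied.
#' @param threshold Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_ice_season <- function(series, metrics = NULL, threshold = 0.5) {
  p <- ggplot2::ggplot(series,
                       ggplot2::aes(x = .data$doy, y = .data$fraction)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$year)) +
    ggplot2::labs(x = "Day of year", y = "Ice-covered fraction") +
    ggplot2::theme_minimal()
  if (!is.null(metrics)) {
    long <- tidyr::pivot_longer(metrics,
                                c("spring_transition", "fall_transition"),
                                names_to = "which", values_to = "doy")
    p <- p + ggplot2::geom_vline(data = long,
                                 ggplot2::aes(xintercept = .data$doy),
                                 color = "firebrick", alpha = 0.6)
  }
  p
}

#' Predicted condition-class probabilities along an ice covariate
#'
#' Evaluates [predict_class_probs()] along a grid of one continuous
#' covariate, holding the others at supplied baseline values, and plots
#' the three class probabilities — the standard way to visualize how
#' earlier ice retreat shifts bears from good to poor condition.
#'
#' @param coefficients Coefficient list (as in [predict_class_probs()]).
#' @param vary Name of the covariate to sweep.
#' @param range Numeric length-2 sweep range.
#' @param baseline Named list of the remaining design-column values.
#' @param n_grid Grid size.
#' @return A ggplot object.
#' @export
plot_class_probs <- function(coefficients, vary = "springtran",
                             range = c(130, 190), baseline, n_grid = 100) {
  grid <- seq(range[1], range[2], length.out = n_grid)
  design <- purrr::map_dfr(grid, function(v) {
    row <- as.list(baseline)
    row[[vary]] <- v
    row <- tibble::as_tibble(row)
    dplyr::mutate(row,
      afwc_springtran = .data$afwc * .data$springtran,
      afwc_durfree_lag1 = .data$afwc * .data$durfree_lag1,
      sub_springtran = .data$sub * .data$springtran,
      sub_durfree_lag1 = .data$sub * .data$durfree_lag1,
      am_springtran = .data$am * .data$springtran,
      am_durfree_lag1 = .data$am * .data$durfree_lag1
    )
  })
  probs <- predict_class_probs(coefficients, design)
  df <- tibble::tibble(x = grid, `BCS 1 (poor)` = probs$p1,
                       `BCS 2 (fair)` = probs$p2,
                       `BCS 3 (good)` = probs$p3) |>
    tidyr::pivot_longer(-"x", names_to = "class", values_to = "p")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$p,
                                   color = .data$class)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = vary, y = "Probability", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a projected litter-size trajectory
#'
#' Across-iteration mean with its 2.5/97.5 percentile band.
#'
#' @param object A `projection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot projection_result
#' @export
autoplot.projection_result <- function(object, ...) {
  ggplot2::ggplot(object$trajectory, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "steelblue",
                       linewidth = 1) +
    ggplot2::coord_cartesian(ylim = c(1, 2)) +
    ggplot2::labs(x = "Year", y = "Mean COY litter size") +
    ggplot2::theme_minimal()
}

#' Plot detected land-use events against the sea-ice transitions
#'
#' @param object A tibble from [detect_land_events()].
#' @param metrics Optional [season_metrics()] tibble drawn as lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot land_use_events
#' @export
autoplot.land_use_events <- function(object, metrics = NULL, ...) {
  df <- tidyr::pivot_longer(object, c("arrival_doy", "departure_doy"),
                            names_to = "event", values_to = "doy") |>
    dplyr::filter(!is.na(.data$doy))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$year, .data$doy,
                                        color = .data$event)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = "Year", y = "Day of year", color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(metrics)) {
    ml <- tidyr::pivot_longer(metrics,
                              c("spring_transition", "fall_transition"),
                              names_to = "event", values_to = "doy")
    p <- p + ggplot2::geom_line(data = ml, linetype = "dashed")
  }
  p
}
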