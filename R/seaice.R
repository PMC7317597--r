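#' Smooth a daily ice-fraction series with a centered running mean
#'
#' Threshold-crossing dates computed on raw daily fractions are sensitive to
#' single-day noise; a short centered running mean stabilizes them. The
#' window must be odd so the mean is centered; `window = 1` is the identity.
#' Endpoints use the available (truncated) window.
#'
#' @param series A data frame with columns `year`, `doy`, `fraction` for one
#'   or more years of daily ice-covered fraction of the region.
#' @param window Odd integer window length in days.
#' @return A tibble with the same columns, `fraction` smoothed within year.
#' @export
smooth_series <- function(series, window = 5) {
  stopifnot(is.data.frame(series))
  if (length(window) != 1 || window < 1 || window %% 2 == 0) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  if (window == 1) {
    return(dplyr::as_tibble(series))
  }
  half <- (window - 1) / 2
  series |>
    dplyr::as_tibble() |>
    dplyr::arrange(.data$year, .data$doy) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(fraction = running_mean(.data$fraction, half)) |>
    dplyr::ungroup()
}

# centered running mean with truncated windows at the ends
running_mean <- function(x, half) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Spring and fall sea-ice transition dates for one year
#'
#' The spring transition is the first day of year on which the (smoothed)
#' ice fraction is strictly below `threshold` and remains below it for at
#' least `persistence` consecutive days; the fall transition is the first
#' day after the spring transition on which the fraction is strictly above
#' `threshold` and remains above it for at least `persistence` days.
#' A fraction exactly equal to the threshold counts as neither below nor
#' above. Brief dips or recoveries shorter than the persistence run are
#' ignored.
#'
#' @param fractions Numeric vector of daily ice fractions (length 365/366),
#'   already smoothed if smoothing is wanted.
#' @param threshold Ice-fraction threshold defining the transitions.
#' @param persistence Minimum run length (days) below/above the threshold.
#' @return A list with `spring` and `fall` day-of-year (1-based); either is
#'   `NA` when the series never makes the corresponding persistent crossing.
#' @export
transition_dates <- function(fractions, threshold = 0.5, persistence = 5) {
  stopifnot(is.numeric(fractions), length(fractions) >= persistence)
  n <- length(fractions)
  below <- fractions < threshold
  spring <- first_persistent(below, persistence, start = 1L)
  if (is.na(spring)) {
    return(list(spring = NA_integer_, fall = NA_integer_))
  }
  above <- fractions > threshold
  fall <- first_persistent(above, persistence, start = spring + 1L)
  list(spring = spring, fall = fall)
}

# first index >= start opening a run of `persistence` TRUEs; runs truncated
# by the end of the series do not qualify
first_persistent <- function(flag, persistence, start) {
  n <- length(flag)
  if (start > n - persistence + 1L) return(NA_integer_)
  r <- rle(flag[start:n])
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= persistence)
  if (length(hit) == 0) return(NA_integer_)
  start + ends[hit[1]] - r$lengths[hit[1]]
}

#' Per-year sea-ice season metrics
#'
#' Computes, for each year of daily ice-fraction data, the spring and fall
#' transition dates (50% threshold by default) and the ice-free duration,
#' defined as the number of days between the spring and fall transitions
#' (half-open interval, so `durfree = fall - spring`).
#'
#' @param series Data frame with columns `year`, `doy`, `fraction`.
#' @param threshold,persistence Passed to [transition_dates()].
#' @param window Smoothing window passed to [smooth_series()].
#' @return A tibble with columns `year`, `spring_transition`,
#'   `fall_transition`, `ice_free_duration`. Years whose series never makes
#'   a persistent crossing carry `NA` metrics (with a warning).
#' @export
season_metrics <- function(series, threshold = 0.5, persistence = 5,
                           window = 5) {
  stopifnot(is.data.frame(series), nrow(series) > 0)
  smoothed <- smooth_series(series, window)
  out <- smoothed |>
    dplyr::group_by(year = .data$year) |>
    dplyr::arrange(.data$doy, .by_group = TRUE) |>
    dplyr::summarise(
      res = list(transition_dates(.data$fraction, threshold, persistence)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      spring_transition = purrr::map_int(.data$res, ~ as.integer(.x$spring)),
      fall_transition   = purrr::map_int(.data$res, ~ as.integer(.x$fall)),
      ice_free_duration = .data$fall_transition - .data$spring_transition
    ) |>
    dplyr::select(-"res")
  if (anyNA(out$spring_transition) || anyNA(out$fall_transition)) {
    bad <- out$year[is.na(out$spring_transition) | is.na(out$fall_transition)]
    warning("no persistent transition found for year(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Ordinary least-squares trend of an annual metric
#'
#' Fits `value ~ year` by OLS and reports the slope, its standard error,
#' the two-sided p-value, and the slope expressed per decade (10 x slope),
#' the scale on which long-term phenology trends are usually quoted.
#'
#' @param years,values Numeric vectors of equal length (>= 3 distinct years).
#' @return A one-row tibble: `slope`, `se`, `p`, `slope_per_decade`,
#'   `intercept`, `n`.
#' @export
fit_trend <- function(years, values) {
  keep <- stats::complete.cases(years, values)
  years <- years[keep]; values <- values[keep]
  if (length(years) < 3) stop("need at least 3 years", call. = FALSE)
  if (length(unique(years)) < 2) {
    stop("years are constant; no trend is identifiable", call. = FALSE)
  }
  fit <- stats::lm(values ~ years)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    slope = unname(sm["years", "Estimate"]),
    se = unname(sm["years", "Std. Error"]),
    p = unname(sm["years", "Pr(>|t|)"]),
    slope_per_decade = 10 * unname(sm["years", "Estimate"]),
    intercept = unname(sm["(Intercept)", "Estimate"]),
    n = length(years)
  )
}

#' Build a linear forward scenario for the sea-ice metrics
#'
#' Fits OLS lines to `spring_transition` and `ice_free_duration` over a
#' window of observed years and packages intercepts and slopes as a
#' scenario that [project_litter_size()] can extrapolate over a future
#' horizon. Two canonical presets reflect the sensitivity analysis usually
#' run for this system: `"declining"` (spring slope -0.83 d/yr, ice-free
#' duration slope 1.85 d/yr, the 1979-2013 trend) and `"stable"` (spring
#' slope -0.21 d/yr, duration slope 0.29 d/yr, the 2000-2013 trend); see
#' [ice_scenario()].
#'
#' @param metrics Tibble from [season_metrics()].
#' @param fit_window Optional integer vector of years to fit on (default all).
#' @param horizon Number of future years the scenario covers.
#' @param start_year First future year; defaults to one past the window.
#' @param noise_sd Optional interannual noise SD (days); 0 = deterministic.
#' @return An `ice_scenario` object (a list).
#' @export
make_scenario <- function(metrics, fit_window = NULL, horizon = 35,
                          start_year = NULL, noise_sd = 0) {
  stopifnot(is.data.frame(metrics))
  if (is.null(fit_window)) fit_window <- metrics$year
  m <- dplyr::filter(metrics, .data$year %in% fit_window)
  if (nrow(m) < 3) stop("fit window shorter than 3 years", call. = FALSE)
  sp <- fit_trend(m$year, m$spring_transition)
  du <- fit_trend(m$year, m$ice_free_duration)
  if (is.null(start_year)) start_year <- max(m$year) + 1L
  ice_scenario(
    start_year = start_year, horizon = horizon,
    spring_intercept = sp$intercept, spring_slope = sp$slope,
    durfree_intercept = du$intercept, durfree_slope = du$slope,
    noise_sd = noise_sd
  )
}

#' Construct an ice scenario directly or from a named preset
#'
#' @param preset Optional `"declining"` or `"stable"`; supplies the slopes
#'   described in [make_scenario()]. Intercepts then locate the lines at
#'   `start_year` via `spring_at_start` / `durfree_at_start`.
#' @param start_year,horizon First projected year and number of years.
#' @param spring_intercept,spring_slope,durfree_intercept,durfree_slope
#'   Line parameters in day-of-year (resp. days) against calendar year.
#' @param spring_at_start,durfree_at_start Convenience anchors used with
#'   `preset`: metric values in the first projected year.
#' @param noise_sd Interannual noise SD in days (0 = deterministic lines).
#' @return An `ice_scenario` object.
#' @export
ice_scenario <- function(preset = NULL, start_year = 2014, horizon = 35,
                         spring_intercept = NULL, spring_slope = NULL,
                         durfree_intercept = NULL, durfree_slope = NULL,
                         spring_at_start = 160, durfree_at_start = 95,
                         noise_sd = 0) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("declining", "stable"))
    slopes <- switch(preset,
      declining = c(spring = -0.83, durfree = 1.85),
      stable    = c(spring = -0.21, durfree = 0.29)
    )
    spring_slope <- unname(slopes["spring"])
    durfree_slope <- unname(slopes["durfree"])
    spring_intercept <- spring_at_start - spring_slope * start_year
    durfree_intercept <- durfree_at_start - durfree_slope * start_year
  }
  stopifnot(horizon > 0, !is.null(spring_slope), !is.null(durfree_slope))
  structure(
    list(
      start_year = start_year, horizon = as.integer(horizon),
      spring_intercept = spring_intercept, spring_slope = spring_slope,
      durfree_intercept = durfree_intercept, durfree_slope = durfree_slope,
      noise_sd = noise_sd, preset = preset %||% "fitted"
    ),
    class = "ice_scenario"
  )
}

#' Evaluate scenario covariates over the projection horizon
#'
#' Returns, for each future year, the projected spring transition date and
#' the projected ice-free duration of the *previous* year (the lag-1
#' covariate the condition and litter-size models use).
#'
#' @param scenario An `ice_scenario`.
#' @param seed Optional seed used only when `noise_sd > 0`.
#' @return Tibble with `year`, `springtran`, `durfree_lag1`.
#' @export
scenario_covariates <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "ice_scenario"))
  yrs <- scenario$start_year + seq_len(scenario$horizon) - 1L
  springtran <- scenario$spring_intercept + scenario$spring_slope * yrs
  durfree_lag1 <- scenario$durfree_intercept + scenario$durfree_slope * (yrs - 1)
  if (scenario$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    springtran <- springtran + stats::rnorm(length(yrs), 0, scenario$noise_sd)
    durfree_lag1 <- durfree_lag1 + stats::rnorm(length(yrs), 0, scenario$noise_sd)
  }
  tibble::tibble(year = yrs, springtran = springtran,
                 durfree_lag1 = durfree_lag1)
}

#' @export
print.ice_scenario <- function(x, ...) {
  cat("<ice_scenario> (", x$preset, ")\n", sep = "")
  cat("  years ", x$start_year, "-", x$start_year + x$horizon - 1L, "\n", sep = "")
  cat(sprintf("  spring transition: %.2f %+.3f d/yr\n",
              x$spring_intercept, x$spring_slope))
  cat(sprintf("  ice-free duration: %.2f %+.3f d/yr\n",
              x$durfree_intercept, x$durfree_slope))
  invisible(x)
}
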