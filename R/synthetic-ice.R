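#' Ground truth for the synthetic sea-ice generator
#'
#' Parametrizes a family of seasonal ice-fraction curves: a winter plateau
#' near full cover, a sigmoidal melt ramp crossing 50% at the spring
#' transition date, a summer trough near zero, and a sigmoidal freeze ramp
#' crossing 50% at the fall transition date. Transition dates drift
#' linearly across years with additive interannual noise, emulating the
#' long-term spring retreat and fall advance trends observed in seasonal
#' ice regions such as Baffin Bay.
#'
#' @param base_spring_doy,base_fall_doy Expected transition days-of-year in
#'   the first simulated year. Defaults give a mid-June retreat and a
#'   mid-November advance with a ~95 d ice-free season.
#' @param spring_slope,fall_slope Linear drift of each transition in
#'   days/year. The defaults (-0.83 and +0.5) match the long-term declining
#'   trend reported for Baffin Bay (spring retreat ~8 d/decade earlier,
#'   fall advance ~5 d/decade later).
#' @param interannual_sd SD (days) of year-to-year noise on each transition.
#' @param melt_width Steepness scale (days) of the seasonal sigmoids.
#' @return An `ice_truth` object (a validated list).
#' @export
ice_truth <- function(base_spring_doy = 170, base_fall_doy = 315,
                      spring_slope = -0.83, fall_slope = 0.5,
                      interannual_sd = 6, melt_width = 7) {
  if (melt_width <= 0) stop("`melt_width` must be positive", call. = FALSE)
  if (interannual_sd < 0) stop("`interannual_sd` must be >= 0", call. = FALSE)
  if (base_spring_doy >= base_fall_doy) {
    stop("spring transition must precede fall transition", call. = FALSE)
  }
  structure(
    list(base_spring_doy = base_spring_doy, base_fall_doy = base_fall_doy,
         spring_slope = spring_slope, fall_slope = fall_slope,
         interannual_sd = interannual_sd, melt_width = melt_width),
    class = "ice_truth"
  )
}

# double-sigmoid seasonal curve: ~1 in winter, ~0 between spring and fall
seasonal_fraction <- function(doy, spring, fall, width) {
  1 - (plogis((doy - spring) / width) - plogis((doy - fall) / width))
}

#' Generate daily sea-ice fraction series with known transition truth
#'
#' One series per year. Each year's true spring/fall transitions are the
#' base dates plus linear drift plus Gaussian interannual noise; the daily
#' fractions follow a double-sigmoid through those dates, optionally with
#' small daily observation noise clipped to \[0, 1\].
#'
#' @param truth An [ice_truth()] object.
#' @param years Integer vector of calendar years (non-empty).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param daily_noise_sd SD of additive daily noise on the fraction scale.
#' @return A list with `series` (tibble: `year`, `doy`, `fraction`) and
#'   `truth_dates` (tibble: `year`, `spring_true`, `fall_true`).
#' @export
gen_ice_series <- function(truth, years, seed = 1, daily_noise_sd = 0.02) {
  stopifnot(inherits(truth, "ice_truth"))
  if (length(years) == 0) stop("`years` must be non-empty", call. = FALSE)
  set.seed(seed)
  offset <- years - years[1]
  spring <- truth$base_spring_doy + truth$spring_slope * offset +
    rnorm(length(years), 0, truth$interannual_sd)
  fall <- truth$base_fall_doy + truth$fall_slope * offset +
    rnorm(length(years), 0, truth$interannual_sd)
  # keep the season well-formed even in extreme noise draws
  fall <- pmax(fall, spring + 8 * truth$melt_width)
  series <- purrr::map2_dfr(seq_along(years), years, function(i, y) {
    nd <- days_in_year(y)
    doy <- seq_len(nd)
    fr <- seasonal_fraction(doy, spring[i], fall[i], truth$melt_width)
    if (daily_noise_sd > 0) {
      fr <- pmin(pmax(fr + rnorm(nd, 0, daily_noise_sd), 0), 1)
    }
    tibble::tibble(year = y, doy = doy, fraction = fr)
  })
  list(
    series = series,
    truth_dates = tibble::tibble(year = years, spring_true = spring,
                                 fall_true = fall)
  )
}
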