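#' Default Argos location-class error SDs (km)
#'
#' One-dimensional positional error SD per Argos quality class, consistent
#' with classes 0-3 having errors of roughly 1.5 km or less while A/B/Z
#' carry no predicted accuracy. Configurable wherever used.
#' @export
argos_error_km <- c(`3` = 0.25, `2` = 0.5, `1` = 1.5, `0` = 5,
                    A = 10, B = 20, Z = 50)

# default class frequencies; not calibrated to any fleet, merely plausible
argos_class_freq <- c(`3` = 0.12, `2` = 0.18, `1` = 0.30, `0` = 0.18,
                      A = 0.12, B = 0.08, Z = 0.02)

#' Generate duty-cycled Argos-like telemetry tracks with known land-use truth
#'
#' Each simulated bear spends an offshore season approaching the coast at a
#' constant swimming/walking speed, comes ashore at a true arrival date tied
#' to that year's spring ice transition, remains on land, and departs at a
#' true departure date tied to the fall transition. Collars transmit during
#' one 6-h window around midday every `duty_cycle` days, producing several
#' fixes per transmit day with class-dependent positional noise. The true
#' event dates are returned alongside the fixes so detector recovery can be
#' scored exactly.
#'
#' @param ice_metrics Tibble from [season_metrics()] (one row per year).
#' @param coastline A [gen_coastline()] object.
#' @param n_bears Number of bear-years to simulate (> 0).
#' @param duty_cycle Days between transmit days (1-6).
#' @param quality_error_km Named vector of per-class error SDs (km).
#' @param class_freq Named sampling frequencies over quality classes.
#' @param seed Integer seed.
#' @param approach_kmd Cross-shore approach/departure speed (km/day).
#' @param arrival_lag_mean,arrival_lag_sd Days between the spring ice
#'   transition and true arrival on land (bears follow the receding ice,
#'   so arrival trails the 50% transition).
#' @param departure_lag_mean,departure_lag_sd Days between true departure
#'   and the fall transition (bears leave as ice re-forms).
#' @param fixes_per_day Fixes within each transmit window.
#' @param denning_prob Probability a bear-year is flagged as denning (its
#'   spring departure is then dictated by the den, not the ice).
#' @return List with `fixes` (tibble: `bear_id`, `timestamp`, `lat`, `lon`,
#'   `quality`) and `truth` (tibble: `bear_id`, `year`, `arrival_doy`,
#'   `departure_doy`, `denning`).
#' @export
gen_tracks <- function(ice_metrics, coastline, n_bears = 20, duty_cycle = 4,
                       quality_error_km = argos_error_km,
                       class_freq = argos_class_freq, seed = 1,
                       approach_kmd = 6,
                       arrival_lag_mean = 25, arrival_lag_sd = 8,
                       departure_lag_mean = 8, departure_lag_sd = 6,
                       fixes_per_day = 3, denning_prob = 0) {
  stopifnot(inherits(coastline, "coastline"))
  if (!duty_cycle %in% 1:6) stop("`duty_cycle` must be in 1..6", call. = FALSE)
  if (n_bears <= 0) stop("`n_bears` must be > 0", call. = FALSE)
  metrics <- dplyr::filter(ice_metrics, !is.na(.data$spring_transition),
                           !is.na(.data$fall_transition))
  if (nrow(metrics) == 0) stop("`ice_metrics` is empty", call. = FALSE)
  set.seed(seed)
  lat_rng <- coastline$extent$lat
  km_per_deg_lat <- 111.195

  rows <- purrr::map_dfr(seq_len(n_bears), function(b) {
    m <- metrics[((b - 1) %% nrow(metrics)) + 1, ]
    lat_b <- runif(1, lat_rng[1] + 0.15 * diff(lat_rng),
                   lat_rng[2] - 0.15 * diff(lat_rng))
    arrival <- m$spring_transition +
      max(rnorm(1, arrival_lag_mean, arrival_lag_sd), 3)
    departure <- m$fall_transition -
      rnorm(1, departure_lag_mean, departure_lag_sd)
    departure <- max(departure, arrival + 30)
    km_per_deg_lon <- km_per_deg_lat * cos(lat_b * pi / 180)
    lon_c <- coast_lon_at(coastline, lat_b)
    days <- seq(floor(m$spring_transition - 50),
                ceiling(max(m$fall_transition, departure) + 20),
                by = duty_cycle)
    denning <- runif(1) < denning_prob
    purrr::map_dfr(days, function(d) {
      # signed distance (km) to the land edge along the bear's latitude:
      # positive offshore, negative inland
      dist_land <- if (d < arrival) {
        approach_kmd * (arrival - d)
      } else if (d <= departure) {
        -5
      } else {
        approach_kmd * (d - departure)
      }
      dist_land <- min(dist_land, 250)
      hours <- sort(runif(fixes_per_day, 9, 15))
      quality <- sample(names(class_freq), fixes_per_day, replace = TRUE,
                        prob = class_freq)
      err_sd <- unname(quality_error_km[quality])
      tibble::tibble(
        bear_id = sprintf("B%03d", b),
        year = m$year,
        timestamp = as.POSIXct(sprintf("%d-01-01 00:00:00", m$year),
                               tz = "UTC") +
          ((d - 1) * 24 + hours) * 3600,
        lat = lat_b + rnorm(fixes_per_day, 0, err_sd) / km_per_deg_lat,
        lon = lon_c + dist_land / km_per_deg_lon +
          rnorm(fixes_per_day, 0, err_sd) / km_per_deg_lon,
        quality = quality,
        denning = denning,
        arrival_doy = arrival,
        departure_doy = departure
      )
    })
  })
  rows <- dplyr::arrange(rows, .data$bear_id, .data$timestamp)
  truth <- rows |>
    dplyr::distinct(.data$bear_id, .data$year, .data$arrival_doy,
                    .data$departure_doy, .data$denning)
  list(
    fixes = dplyr::select(rows, "bear_id", "timestamp", "lat", "lon",
                          "quality"),
    truth = truth
  )
}
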