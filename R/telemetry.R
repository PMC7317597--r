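#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

# interior turning angle (degrees) at B of the path A-B-C, from the
# great-circle side lengths via the planar law of cosines (adequate at
# movement scales of a few km)
turning_angle <- function(latA, lonA, latB, lonB, latC, lonC) {
  a <- great_circle_km(latB, lonB, latA, lonA)
  c <- great_circle_km(latB, lonB, latC, lonC)
  b <- great_circle_km(latA, lonA, latC, lonC)
  cosang <- (a^2 + c^2 - b^2) / (2 * a * c)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Speed-and-angle filter for Argos tracks
#'
#' Removes implausible fixes per bear: first, sharp out-and-back spikes
#' (turning angle below an angle limit while both adjacent legs exceed the
#' paired distance limit), then fixes implying travel faster than
#' `vmax_kmh` between retained neighbours (the interior fix with the worst
#' excess is removed iteratively). The first and last fix of a track are
#' never removed. Tracks with fewer than 3 fixes are returned unchanged
#' with a warning.
#'
#' @param fixes Tibble with `bear_id`, `timestamp`, `lat`, `lon` (and any
#'   other columns, which are preserved).
#' @param vmax_kmh Maximum plausible speed (km/h).
#' @param spike_angles Angle limits (degrees) for the two spike rules.
#' @param spike_dists Paired leg-distance limits (km).
#' @return The retained fixes, ordered by bear and time.
#' @export
sda_filter <- function(fixes, vmax_kmh = 10, spike_angles = c(15, 25),
                       spike_dists = c(2.5, 5)) {
  fixes <- dplyr::arrange(fixes, .data$bear_id, .data$timestamp)
  out <- fixes |>
    dplyr::group_by(.data$bear_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        warning("bear ", key$bear_id, ": fewer than 3 fixes, not filtered",
                call. = FALSE)
        return(df)
      }
      keep <- sda_filter_one(df$lat, df$lon, as.numeric(df$timestamp) / 3600,
                             vmax_kmh, spike_angles, spike_dists)
      df[keep, ]
    }) |>
    dplyr::ungroup()
  out
}

sda_filter_one <- function(lat, lon, t_h, vmax, ang, dlim, max_iter = 50) {
  idx <- seq_along(lat)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    n <- length(idx)
    if (n < 3) break
    # spike pass
    i <- 2
    while (i <= length(idx) - 1) {
      p <- idx[i - 1]; q <- idx[i]; r <- idx[i + 1]
      din <- great_circle_km(lat[q], lon[q], lat[p], lon[p])
      dout <- great_circle_km(lat[q], lon[q], lat[r], lon[r])
      angle <- turning_angle(lat[p], lon[p], lat[q], lon[q], lat[r], lon[r])
      leg <- min(din, dout)
      if ((leg > dlim[1] && angle < ang[1]) ||
          (leg > dlim[2] && angle < ang[2])) {
        idx <- idx[-i]; changed <- TRUE
      } else {
        i <- i + 1
      }
    }
    # speed pass: drop the interior fix with the largest excess speed
    repeat {
      n <- length(idx)
      if (n < 3) break
      d <- great_circle_km(lat[idx[-n]], lon[idx[-n]], lat[idx[-1]], lon[idx[-1]])
      dt <- pmax(t_h[idx[-1]] - t_h[idx[-n]], 1e-6)
      v <- d / dt
      bad <- which(v > vmax)
      if (length(bad) == 0) break
      # excess attributable to each interior fix = max speed of its two legs
      exc <- rep(0, n)
      exc[bad] <- pmax(exc[bad], v[bad])
      exc[bad + 1] <- pmax(exc[bad + 1], v[bad])
      exc[c(1, n)] <- 0
      if (all(exc == 0)) break  # only an endpoint pair violates
      idx <- idx[-which.max(exc)]
      changed <- TRUE
    }
    if (!changed) break
  }
  idx
}

#' Reduce filtered fixes to one best daily position
#'
#' Within the period of peak satellite passage each day (12:00 UTC +/- 3 h
#' by default), keeps the highest-quality fix, with ties broken by the
#' earliest timestamp. Only Argos qualities 1-3 ever survive; days with no
#' qualifying fix yield no position.
#'
#' @param fixes Filtered fixes tibble (`bear_id`, `timestamp`, `lat`,
#'   `lon`, `quality`).
#' @param peak_hours UTC hour window `c(start, end)` of peak passage.
#' @return Tibble with at most one row per bear-day, plus a `date` column.
#' @export
daily_best_position <- function(fixes, peak_hours = c(9, 15)) {
  fixes |>
    dplyr::mutate(
      date = as.Date(.data$timestamp),
      hour = as.numeric(format(.data$timestamp, "%H")) +
        as.numeric(format(.data$timestamp, "%M")) / 60
    ) |>
    dplyr::filter(.data$quality %in% c("1", "2", "3"),
                  .data$hour >= peak_hours[1], .data$hour <= peak_hours[2]) |>
    dplyr::arrange(.data$bear_id, .data$date,
                   dplyr::desc(.data$quality), .data$timestamp) |>
    dplyr::distinct(.data$bear_id, .data$date, .keep_all = TRUE) |>
    dplyr::select(-"hour")
}

#' Thin daily positions to a strict k-day interval
#'
#' Greedy forward selection per bear: the first position anchors the
#' series; thereafter the next retained position is the first one at least
#' `k` days after the last retained. When positions exist every day the
#' result is an exact k-day grid; where the source series is ragged the
#' gap at a re-anchor may exceed `k` (and is handled downstream by the
#' gap rules of [detect_land_events()]).
#'
#' @param positions Daily positions from [daily_best_position()].
#' @param k Interval in days (4, 5, or 6).
#' @return The thinned positions.
#' @export
resample_interval <- function(positions, k) {
  if (!k %in% 4:6) stop("`k` must be 4, 5, or 6", call. = FALSE)
  positions |>
    dplyr::arrange(.data$bear_id, .data$date) |>
    dplyr::group_by(.data$bear_id) |>
    dplyr::group_modify(function(df, key) {
      keep <- logical(nrow(df))
      keep[1] <- TRUE
      last <- df$date[1]
      for (i in seq_len(nrow(df))[-1]) {
        if (as.numeric(df$date[i] - last) >= k) {
          keep[i] <- TRUE
          last <- df$date[i]
        }
      }
      df[keep, ]
    }) |>
    dplyr::ungroup()
}

#' Classify positions against a buffered coastline
#'
#' A position is "on land" when it lies within `buffer_km` of the land
#' polygon (boundary inclusive). Distances use a local planar projection
#' of the synthetic coastline (adequate for the toy geometry); the signed
#' distance to the buffer boundary is negative inside the buffer.
#'
#' @param positions Tibble with `lat`, `lon`.
#' @param coastline A [gen_coastline()] object (required).
#' @param buffer_km Buffer width around land (km).
#' @return `positions` with added `dist_buffer_km` and `on_land` columns.
#' @export
on_land <- function(positions, coastline, buffer_km = 5) {
  if (missing(coastline) || !inherits(coastline, "coastline")) {
    stop("a `coastline` object is required", call. = FALSE)
  }
  bnd <- coastline$boundary
  lat0 <- mean(range(bnd[, "lat"]))
  kx <- 111.195 * cos(lat0 * pi / 180)
  ky <- 111.195
  bx <- bnd[, "lon"] * kx; by <- bnd[, "lat"] * ky
  px <- positions$lon * kx; py <- positions$lat * ky
  d <- dist_to_polyline(px, py, bx, by)
  inside <- mgcv::in.out(cbind(bx, by), cbind(px, py))
  signed_land <- ifelse(inside, -d, d)
  dplyr::mutate(dplyr::as_tibble(positions),
                dist_buffer_km = signed_land - buffer_km,
                on_land = .data$dist_buffer_km <= 0)
}

# minimum distance from points to a closed polyline, by segments
dist_to_polyline <- function(px, py, bx, by) {
  n <- length(bx)
  best <- rep(Inf, length(px))
  for (i in seq_len(n - 1)) {
    x1 <- bx[i]; y1 <- by[i]; x2 <- bx[i + 1]; y2 <- by[i + 1]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
    d <- sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
    best <- pmin(best, d)
  }
  best
}

#' Detect onshore arrival and departure events
#'
#' Per bear: the arrival is the first entry into the coastal buffer that
#' is followed by at least `persistence` days continuously classified on
#' land; the departure is the symmetric first exit followed by
#' `persistence` days continuously off land. For bracketing positions
#' separated by at most `max_gap` days the event date is the day on which
#' the linearly interpolated signed distance to the buffer boundary
#' crosses zero (floored to a whole day). Wider gaps void the event and
#' flag it `long-gap`, except the swimming exception: when the pre-gap
#' position is offshore in open water (daily ice fraction below
#' `open_water_frac`) and the post-gap position is on land, gaps of
#' `swim_gap` days are admitted with the arrival placed at the first
#' on-land position and flagged `offshore-swim-gap`. Departures of
#' denning-flagged bears are excluded (`denning` flag); tracks ending
#' inside a persistence window leave the event date missing (`track-end`).
#'
#' @param positions Classified daily/k-day positions; must carry
#'   `bear_id`, `date`, `lat`, plus `dist_buffer_km`/`on_land` (computed
#'   via [on_land()] if absent, in which case `coastline` is required).
#' @param coastline Optional [gen_coastline()] object.
#' @param ice_series Optional daily ice series (`year`, `doy`, `fraction`)
#'   used by the swimming exception; without it the exception never fires.
#' @param persistence Days of continuous classification required (14).
#' @param max_gap Largest bracketing gap (days) interpolated normally.
#' @param swim_gap Admissible gap range (days) for the swim exception.
#' @param open_water_frac Ice fraction below which water counts as open.
#' @param buffer_km Buffer width, used when classification is computed here.
#' @param denning_ids Character vector of bear ids whose departure is
#'   den-driven and must be excluded.
#' @return A tibble of land-use events: `bear_id`, `year`, `arrival_doy`,
#'   `departure_doy`, `duration_days`, `arrival_lat`, `departure_lat`,
#'   `exclusion_flags` (comma-separated, possibly empty).
#' @export
detect_land_events <- function(positions, coastline = NULL, ice_series = NULL,
                               persistence = 14, max_gap = 8,
                               swim_gap = c(12, 30), open_water_frac = 0.15,
                               buffer_km = 5, denning_ids = character()) {
  if (!all(c("dist_buffer_km", "on_land") %in% names(positions))) {
    positions <- on_land(positions, coastline, buffer_km)
  }
  out <- positions |>
    dplyr::arrange(.data$bear_id, .data$date) |>
    dplyr::group_by(.data$bear_id) |>
    dplyr::group_modify(function(df, key) {
      detect_events_one(df, key$bear_id, ice_series, persistence, max_gap,
                        swim_gap, open_water_frac,
                        key$bear_id %in% denning_ids)
    }) |>
    dplyr::ungroup()
  class(out) <- c("land_use_events", class(out))
  out
}

detect_events_one <- function(df, id, ice_series, persistence, max_gap,
                              swim_gap, open_water_frac, denning) {
  yr <- as.integer(format(df$date[1], "%Y"))
  t <- as.numeric(df$date - as.Date(sprintf("%d-01-01", yr))) + 1  # doy scale
  land <- df$on_land
  s <- df$dist_buffer_km
  flags <- character()
  n <- nrow(df)

  persistent_from <- function(i, state) {
    # TRUE if classification equals `state` continuously for >= persistence
    # days starting at position i, with coverage to the end of the window
    t_end <- t[i] + persistence
    j <- which(t >= t[i] & t <= t_end)
    if (t[n] < t_end) return(NA)  # track ends inside the window
    all(land[j] == state)
  }

  find_event <- function(entering) {
    # entering=TRUE: first off->on transition with persistent on-land run
    state <- entering
    cand <- which(land == state)
    for (i in cand) {
      if (i > 1 && land[i - 1] == state) next
      ok <- persistent_from(i, state)
      if (is.na(ok)) return(list(idx = i, status = "track-end"))
      if (ok) return(list(idx = i, status = "ok"))
    }
    list(idx = NA_integer_, status = "none")
  }

  event_date <- function(i) {
    # date the signed buffer distance crosses zero between i-1 and i
    if (i == 1) return(list(doy = NA_real_, flag = "track-start"))
    gap <- t[i] - t[i - 1]
    if (gap <= max_gap) {
      frac <- s[i - 1] / (s[i - 1] - s[i])
      frac <- min(max(frac, 0), 1)
      return(list(doy = floor(t[i - 1] + gap * frac), flag = NA_character_))
    }
    # swimming exception: offshore in open water, then ashore
    if (!is.null(ice_series) && gap >= swim_gap[1] && gap <= swim_gap[2] &&
        s[i - 1] > 0 && s[i] <= 0) {
      ice <- ice_series[ice_series$year == yr, ]
      fr <- ice$fraction[match(round(t[i - 1]), ice$doy)]
      if (!is.na(fr) && fr < open_water_frac) {
        return(list(doy = floor(t[i]), flag = "offshore-swim-gap"))
      }
    }
    list(doy = NA_real_, flag = "long-gap")
  }

  arr <- find_event(entering = TRUE)
  arrival <- NA_real_; arrival_lat <- NA_real_
  if (!is.na(arr$idx) && arr$status == "ok") {
    ed <- event_date(arr$idx)
    arrival <- ed$doy
    arrival_lat <- df$lat[arr$idx]
    if (!is.na(ed$flag)) flags <- c(flags, ed$flag)
  } else if (!is.na(arr$idx) && arr$status == "track-end") {
    flags <- c(flags, "track-end")
  }

  departure <- NA_real_; departure_lat <- NA_real_
  if (!is.na(arr$idx) && arr$status == "ok") {
    after <- which(!land & seq_len(n) > arr$idx)
    dep <- NULL
    for (i in after) {
      if (!land[i - 1]) next  # want an on->off edge
      ok <- persistent_from(i, FALSE)
      if (is.na(ok)) { dep <- list(idx = i, status = "track-end"); break }
      if (ok) { dep <- list(idx = i, status = "ok"); break }
    }
    if (!is.null(dep) && dep$status == "ok") {
      if (denning) {
        flags <- c(flags, "denning")
      } else {
        ed <- event_date(dep$idx)
        departure <- ed$doy
        departure_lat <- df$lat[dep$idx - 1]
        if (!is.na(ed$flag)) flags <- c(flags, ed$flag)
      }
    } else if (!is.null(dep) && dep$status == "track-end") {
      flags <- c(flags, "track-end")
    }
  }

  tibble::tibble(
    year = yr,
    arrival_doy = arrival,
    departure_doy = departure,
    duration_days = ifelse(is.na(arrival) | is.na(departure),
                           NA_real_, departure - arrival),
    arrival_lat = arrival_lat,
    departure_lat = departure_lat,
    exclusion_flags = paste(unique(flags), collapse = ",")
  )
}

#' Decadal summary of land-use phenology
#'
#' Means, SDs and sample sizes per decade for arrival date, departure
#' date, duration on land, and event latitudes; Welch two-sided t-tests
#' between the decades; and long-term trends (in days/decade) of arrival
#' and departure dates across years via [fit_trend()].
#'
#' @param events Tibble from [detect_land_events()].
#' @return A list with tibbles `stats`, `tests`, `trends`.
#' @export
phenology_summary <- function(events) {
  ev <- dplyr::mutate(events, decade = decade_of(.data$year))
  vars <- c("arrival_doy", "departure_doy", "duration_days",
            "arrival_lat", "departure_lat")
  stats_tbl <- ev |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "metric") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$metric, .data$decade) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  tests_tbl <- purrr::map_dfr(vars, function(v) {
    a <- ev[[v]][ev$decade == "1990s"]
    b <- ev[[v]][ev$decade == "2000s"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      message("phenology: t-test skipped for ", v, " (group n < 2)")
      return(tibble::tibble(metric = v, difference = NA_real_, p = NA_real_))
    }
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(tt)) {
      message("phenology: t-test skipped for ", v, " (constant data)")
      return(tibble::tibble(metric = v, difference = mean(b) - mean(a),
                            p = NA_real_))
    }
    tibble::tibble(metric = v, difference = mean(b) - mean(a), p = tt$p.value)
  })
  trends_tbl <- purrr::map_dfr(c("arrival_doy", "departure_doy"), function(v) {
    ok <- !is.na(ev[[v]])
    if (sum(ok) < 3 || length(unique(ev$year[ok])) < 2) {
      return(tibble::tibble(metric = v, slope_per_decade = NA_real_,
                            p = NA_real_))
    }
    tr <- fit_trend(ev$year[ok], ev[[v]][ok])
    tibble::tibble(metric = v, slope_per_decade = tr$slope_per_decade,
                   p = tr$p)
  })
  list(stats = stats_tbl, tests = tests_tbl, trends = trends_tbl)
}
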