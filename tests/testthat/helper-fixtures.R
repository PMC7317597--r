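# Shared fixtures and independent oracles, all built in code.

# rectangular toy coastline: land occupies lon < -65 inside the box
toy_coastline <- function() {
  boundary <- cbind(lon = c(-65, -65, -75, -75, -65),
                    lat = c(66, 74, 74, 66, 66))
  structure(
    list(boundary = boundary,
         coast_edge = tibble::tibble(lat = c(66, 74), lon = c(-65, -65)),
         extent = list(lon = c(-75, -55), lat = c(66, 74))),
    class = "coastline"
  )
}

# constant-date toy ice metrics
toy_metrics <- function(years = 1990:2013, spring = 170, fall = 315) {
  tibble::tibble(year = years, spring_transition = as.integer(spring),
                 fall_transition = as.integer(fall),
                 ice_free_duration = as.integer(fall - spring))
}

# brute-force transition scan: first day opening a persistent run
brute_transitions <- function(f, threshold = 0.5, persistence = 5) {
  n <- length(f)
  runs_ok <- function(flag, from) {
    if (from > n) return(NA_integer_)
    for (d in from:n) {
      if (d + persistence - 1 > n) return(NA_integer_)
      if (all(flag[d:(d + persistence - 1)])) return(d)
    }
    NA_integer_
  }
  spring <- runs_ok(f < threshold, 1L)
  fall <- if (is.na(spring) || spring + 1 > n) NA_integer_ else
    runs_ok(f > threshold, spring + 1L)
  list(spring = spring, fall = fall)
}

# closed-form simple OLS
ols_closed_form <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  b <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  list(slope = b, intercept = yb - b * xb)
}

# brute-force candidate enumeration: all subsets of items respecting
# marginality (items = named blocks + interactions with parent names)
enumerate_oracle <- function(blocks, interactions) {
  items <- c(names(blocks), purrr::map_chr(interactions, "term"))
  ni <- length(items)
  out <- list()
  for (mask in 0:(2^ni - 1)) {
    sel <- items[bitwAnd(mask, 2^(seq_len(ni) - 1)) > 0]
    ok <- TRUE
    for (ia in interactions) {
      if (ia$term %in% sel && !all(ia$parents %in% sel)) { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1]] <- sel
  }
  out
}

# positions table with precomputed buffer distances, for event-detector
# tests that need exact geometry
positions_from_dist <- function(doys, dist_buffer, year = 2010,
                                bear_id = "T1", lat = 70) {
  tibble::tibble(
    bear_id = bear_id,
    date = as.Date(sprintf("%d-01-01", year)) + (doys - 1),
    lat = lat, lon = -60,
    dist_buffer_km = dist_buffer,
    on_land = dist_buffer <= 0
  )
}
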