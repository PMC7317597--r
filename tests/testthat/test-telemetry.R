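test_that("great-circle distance is a haversine on a 6371-km sphere", {
  expect_equal(great_circle_km(70, -60, 70, -60), 0)
  expect_equal(great_circle_km(0, 0, 0, 1), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  d1 <- great_circle_km(66, -70, 71, -55)
  d2 <- great_circle_km(71, -55, 66, -70)
  expect_equal(d1, d2)
})

test_that("speed-and-angle filter removes spikes and speeders only", {
  ts0 <- as.POSIXct("2010-07-01 00:00:00", tz = "UTC")
  # 3 collinear fixes at ~5 km/h: all retained
  slow <- tibble::tibble(
    bear_id = "A", timestamp = ts0 + c(0, 1, 2) * 3600,
    lat = 70 + c(0, 0.045, 0.09), lon = -60, quality = "3")
  expect_equal(nrow(sda_filter(slow)), 3)
  # middle fix displaced so both legs imply ~20 km/h: removed
  fast <- slow
  fast$lat[2] <- 70 + 0.18
  out <- sda_filter(fast)
  expect_equal(nrow(out), 2)
  expect_equal(out$lat, fast$lat[c(1, 3)])
  # out-and-back 6-km spike with a ~10 degree interior angle: removed
  spike <- tibble::tibble(
    bear_id = "A", timestamp = ts0 + c(0, 12, 24) * 3600,
    lat = c(70, 70 + 6 / 111.195, 70.009), lon = c(-60, -59.97, -60),
    quality = "3")
  ang <- icebears:::turning_angle(spike$lat[1], spike$lon[1], spike$lat[2],
                                  spike$lon[2], spike$lat[3], spike$lon[3])
  expect_lt(ang, 15)
  expect_equal(nrow(sda_filter(spike)), 2)
  expect_warning(sda_filter(slow[1:2, ]), "fewer than 3")
})

test_that("filtered tracks contain no retained pair implying over-speed", {
  set.seed(13)
  ts0 <- as.POSIXct("2010-07-01 00:00:00", tz = "UTC")
  for (r in 1:20) {
    n <- 40
    fx <- tibble::tibble(
      bear_id = "R", timestamp = ts0 + cumsum(runif(n, 2, 8)) * 3600,
      lat = 70 + cumsum(rnorm(n, 0, 0.03)),
      lon = -60 + cumsum(rnorm(n, 0, 0.08)), quality = "2")
    out <- sda_filter(fx, vmax_kmh = 10)
    if (nrow(out) >= 3) {
      d <- great_circle_km(out$lat[-nrow(out)], out$lon[-nrow(out)],
                           out$lat[-1], out$lon[-1])
      dt <- diff(as.numeric(out$timestamp)) / 3600
      v <- d / dt
      expect_true(all(v[-length(v)] <= 10 + 1e-9))
    }
  }
})

test_that("daily reduction keeps the first highest-quality peak-window fix", {
  ts0 <- as.POSIXct("2010-07-01 10:00:00", tz = "UTC")
  fx <- tibble::tibble(
    bear_id = "A",
    timestamp = c(ts0, ts0 + 3600, ts0 + 86400, ts0 + 90000,
                  ts0 + 2 * 86400),
    lat = 70 + (0:4) / 100, lon = -60,
    quality = c("1", "3", "2", "2", "A"))
  d <- daily_best_position(fx)
  expect_equal(nrow(d), 2)                     # quality-A day drops out
  expect_equal(d$quality, c("3", "2"))         # best, then earliest tie
  expect_equal(d$lat, c(70.01, 70.02))
})

test_that("interval thinning produces a strict k-day grid on daily data", {
  dates <- as.Date("2010-07-01") + 0:29
  pos <- tibble::tibble(bear_id = "A", date = dates, lat = 70, lon = -60)
  th <- resample_interval(pos, 4)
  expect_equal(as.numeric(diff(th$date)), rep(4, nrow(th) - 1))
  expect_equal(th$date[1], dates[1])
  # already k-spaced input is unchanged (idempotence)
  expect_equal(resample_interval(th, 4), th)
  # ragged series: retained gaps are >= k, and == k whenever a position
  # existed exactly k days after the previously retained one
  set.seed(3)
  for (r in 1:20) {
    keep <- sort(sample(0:59, 30))
    rag <- tibble::tibble(bear_id = "A", date = as.Date("2010-06-01") + keep,
                          lat = 70, lon = -60)
    th2 <- resample_interval(rag, 5)
    gaps <- as.numeric(diff(th2$date))
    expect_true(all(gaps >= 5))
    for (i in seq_along(gaps)) {
      if ((th2$date[i] + 5) %in% rag$date) expect_equal(gaps[i], 5)
    }
  }
  expect_error(resample_interval(pos, 3), "must be 4, 5, or 6")
})

test_that("buffer classification yields correct signed distances", {
  cl <- toy_coastline()
  km_lon <- 111.195 * cos(70 * pi / 180)
  pts <- tibble::tibble(
    lat = 70,
    lon = c(-65 + 10 / km_lon,   # 10 km offshore
            -65 - 3 / km_lon,    # 3 km inland
            -65 + 5 / km_lon))   # exactly on the buffer boundary
  out <- on_land(pts, cl, buffer_km = 5)
  expect_equal(out$dist_buffer_km[1], 5, tolerance = 0.05)
  expect_false(out$on_land[1])
  expect_lt(out$dist_buffer_km[2], 0)
  expect_true(out$on_land[2])
  expect_true(out$on_land[3])  # boundary inclusive
  expect_equal(out$dist_buffer_km[3], 0, tolerance = 0.05)
  expect_error(on_land(pts, buffer_km = 5), "coastline")
})

test_that("event dates come from the signed-distance zero crossing", {
  # off-land day 100 at +25 km, on-land day 104 at -5 km: arrival 103.33,
  # recorded as day 103
  pos <- positions_from_dist(
    doys = c(92, 96, 100, 104, 108, 112, 116, 120, 124),
    dist_buffer = c(85, 55, 25, -5, -5, -5, -5, -5, -5))
  ev <- detect_land_events(pos)
  expect_equal(ev$arrival_doy, 103)
  expect_equal(ev$exclusion_flags, "")
  # interpolated dates lie strictly between the bracketing fixes
  expect_gt(ev$arrival_doy, 100)
  expect_lt(ev$arrival_doy, 104)
})

test_that("persistence, gaps, denning, and the swim exception are honoured", {
  # 10 days inside the buffer then out again: no arrival
  pos <- positions_from_dist(
    doys = seq(80, 140, by = 4),
    dist_buffer = c(40, 30, 20, 10, -2, -2, -2, 10, 20, 30, 40, 50, 60,
                    70, 80, 90))
  ev <- detect_land_events(pos)
  expect_true(is.na(ev$arrival_doy))
  # 16-day gap from open water to land, admissible with ice data
  ice <- tibble::tibble(year = 2010, doy = 1:365,
                        fraction = c(rep(1, 149), rep(0.05, 216)))
  pos2 <- positions_from_dist(
    doys = c(150, 154, 158, 174, 178, 182, 186, 190, 194),
    dist_buffer = c(60, 50, 45, -5, -5, -5, -5, -5, -5))
  ev2 <- detect_land_events(pos2, ice_series = ice)
  expect_equal(ev2$arrival_doy, 174)
  expect_match(ev2$exclusion_flags, "offshore-swim-gap")
  # same gap without open water: voided
  ice_hi <- dplyr::mutate(ice, fraction = 0.6)
  ev3 <- detect_land_events(pos2, ice_series = ice_hi)
  expect_true(is.na(ev3$arrival_doy))
  expect_match(ev3$exclusion_flags, "long-gap")
  # denning females have the departure excluded
  pos4 <- positions_from_dist(
    doys = seq(100, 180, by = 4),
    dist_buffer = c(20, 10, -5, -5, -5, -5, -5, -5, -5, -5, -5, -5, 5,
                    15, 25, 35, 45, 55, 65, 75, 85))
  ev4 <- detect_land_events(pos4, denning_ids = "T1")
  expect_false(is.na(ev4$arrival_doy))
  expect_true(is.na(ev4$departure_doy))
  expect_match(ev4$exclusion_flags, "denning")
  ev5 <- detect_land_events(pos4)
  expect_false(is.na(ev5$departure_doy))
  expect_equal(ev5$duration_days, ev5$departure_doy - ev5$arrival_doy)
})

test_that("the detector recovers generator truth on noise-free tracks", {
  sim <- gen_ice_series(ice_truth(), 1990:2013, seed = 31)
  metrics <- season_metrics(sim$series)
  cl <- gen_coastline(seed = 32)
  noiseless <- setNames(rep(0, 7), c("3", "2", "1", "0", "A", "B", "Z"))
  trk <- gen_tracks(metrics, cl, n_bears = 40, duty_cycle = 4,
                    quality_error_km = noiseless,
                    class_freq = c(`3` = 1), seed = 33)
  daily <- daily_best_position(trk$fixes)
  ev <- detect_land_events(daily, cl, ice_series = sim$series)
  truth <- dplyr::rename(trk$truth, arr_true = "arrival_doy",
                         dep_true = "departure_doy")
  j <- dplyr::inner_join(ev, truth, by = c("bear_id", "year"))
  ok_arr <- !is.na(j$arrival_doy)
  ok_dep <- !is.na(j$departure_doy)
  expect_gt(mean(ok_arr), 0.9)
  expect_gt(mean(ok_dep), 0.9)
  expect_true(all(abs(j$arrival_doy[ok_arr] - j$arr_true[ok_arr]) <= 4))
  expect_true(all(abs(j$departure_doy[ok_dep] - j$dep_true[ok_dep]) <= 4))
})

test_that("phenology summary computes decade stats, tests, and trends", {
  ev <- tibble::tibble(
    bear_id = c("a", "b", "c"), year = c(1993, 1993, 1994),
    arrival_doy = c(230, 240, 250), departure_doy = c(300, 310, 320),
    duration_days = c(70, 70, 70), arrival_lat = 70, departure_lat = 70,
    exclusion_flags = "")
  s <- phenology_summary(ev)
  expect_equal(s$stats$mean[s$stats$metric == "arrival_doy"], 240)
  expect_true(all(is.na(s$tests$p)))  # single decade: tests skipped
  # identical decade groups give p = 1
  ev2 <- dplyr::bind_rows(ev, dplyr::mutate(ev, year = year + 18))
  s2 <- suppressMessages(phenology_summary(ev2))
  expect_equal(s2$tests$p[s2$tests$metric == "arrival_doy"], 1)
})

test_that("a 20-day arrival shift is detected at alpha 0.001", {
  # Monte-Carlo power harness at the observed group sizes and spreads
  set.seed(99)
  reject <- vapply(1:200, function(r) {
    ev <- tibble::tibble(
      bear_id = sprintf("b%02d", 1:76),
      year = c(sample(1992:1996, 30, TRUE), sample(2009:2014, 46, TRUE)),
      arrival_doy = c(rnorm(30, 236, 16), rnorm(46, 216, 11)),
      departure_doy = NA_real_, duration_days = NA_real_,
      arrival_lat = 70, departure_lat = NA_real_, exclusion_flags = "")
    s <- suppressMessages(phenology_summary(ev))
    s$tests$p[s$tests$metric == "arrival_doy"] < 0.001
  }, logical(1))
  expect_gte(mean(reject), 0.99)
})
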