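#' Generate a synthetic coastline polygon
#'
#' Builds a closed land polygon occupying the western part of a lat/lon
#' box, with a roughly meridional coastline whose longitude wanders gently
#' with latitude. This emulates the east-facing coast that bears come
#' ashore on; it makes no claim to spatial realism beyond providing a
#' well-defined land/ocean split for the land-use detector.
#'
#' @param extent List with numeric `lon = c(min, max)` and
#'   `lat = c(min, max)`.
#' @param seed Integer seed.
#' @param n_vertices Number of coastline vertices (south to north).
#' @param coast_frac Fraction of the longitude range occupied by land.
#' @param wiggle_deg SD of the longitude wiggle of the coast (degrees).
#' @return A `coastline` object: list with `boundary` (closed two-column
#'   lon/lat matrix), `coast_edge` (tibble `lat`, `lon` of the seaward
#'   edge), and `extent`.
#' @export
gen_coastline <- function(extent = list(lon = c(-75, -55), lat = c(66, 74)),
                          seed = 1, n_vertices = 41, coast_frac = 0.35,
                          wiggle_deg = 0.1) {
  lon <- extent$lon; lat <- extent$lat
  if (length(lon) != 2 || length(lat) != 2 || diff(lon) <= 0 || diff(lat) <= 0) {
    stop("degenerate extent box", call. = FALSE)
  }
  set.seed(seed)
  lat_v <- seq(lat[1], lat[2], length.out = n_vertices)
  base_lon <- lon[1] + coast_frac * diff(lon)
  wig <- as.numeric(stats::filter(rnorm(n_vertices, 0, wiggle_deg),
                                  rep(1 / 3, 3), sides = 2))
  wig[is.na(wig)] <- 0
  coast_lon <- pmin(pmax(base_lon + wig, lon[1] + 0.05 * diff(lon)),
                    lon[2] - 0.2 * diff(lon))
  boundary <- rbind(
    cbind(coast_lon, lat_v),            # seaward edge, south to north
    c(lon[1], lat[2]),                  # back along the north and west edges
    c(lon[1], lat[1]),
    c(coast_lon[1], lat_v[1])           # close the ring
  )
  colnames(boundary) <- c("lon", "lat")
  structure(
    list(boundary = boundary,
         coast_edge = tibble::tibble(lat = lat_v, lon = coast_lon),
         extent = extent),
    class = "coastline"
  )
}

# seaward-edge longitude at a given latitude, linearly interpolated
coast_lon_at <- function(coastline, lat) {
  stats::approx(coastline$coast_edge$lat, coastline$coast_edge$lon,
                xout = lat, rule = 2)$y
}

#' Write / read a coastline as GeoJSON
#'
#' The polygon is stored as a standard GeoJSON `Polygon` feature
#' (longitude, latitude coordinate order); the seaward-edge table used by
#' the track generator is rebuilt on read from the ring vertices.
#'
#' @param coastline A `coastline` object.
#' @param path File path.
#' @return `write_coastline_geojson()` returns `path` invisibly;
#'   `read_coastline_geojson()` returns a `coastline` object.
#' @export
write_coastline_geojson <- function(coastline, path) {
  stopifnot(inherits(coastline, "coastline"))
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(
        name = "synthetic-land",
        n_coast_vertices = nrow(coastline$coast_edge),
        extent_lon = coastline$extent$lon,
        extent_lat = coastline$extent$lat
      ),
      geometry = list(
        type = "Polygon",
        coordinates = list(unname(lapply(
          seq_len(nrow(coastline$boundary)),
          function(i) as.numeric(coastline$boundary[i, ])
        )))
      )
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' @rdname write_coastline_geojson
#' @export
read_coastline_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feat <- gj$features[[1]]
  ring <- feat$geometry$coordinates[[1]]
  boundary <- do.call(rbind, lapply(ring, function(p) unlist(p)))
  colnames(boundary) <- c("lon", "lat")
  ncv <- feat$properties$n_coast_vertices
  structure(
    list(boundary = boundary,
         coast_edge = tibble::tibble(lat = boundary[seq_len(ncv), "lat"],
                                     lon = boundary[seq_len(ncv), "lon"]),
         extent = list(lon = unlist(feat$properties$extent_lon),
                       lat = unlist(feat$properties$extent_lat))),
    class = "coastline"
  )
}
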