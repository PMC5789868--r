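# Trip distances between stations.
#
# A "trip" is an unordered pair of stations visited by consecutive detections
# of one tag. The distance rule mirrors the QC procedure:
#   * straight (great-circle) when the straight line stays over water, or
#     when both stations sit on the same river installation (rasterised maps
#     are too coarse for small river systems, so river geometry is handled
#     explicitly rather than through the raster);
#   * least-cost through the water graph when the straight line crosses land;
#   * river_composite when a river station is paired with a station elsewhere:
#     each river endpoint is first routed to its nearest coastline point by a
#     straight leg, and the over-water rule is then applied between those
#     coastal points; the trip distance is the sum of the legs.
# Results are memoised per unordered station pair, since tags revisit the
# same trips many times.

#' Create an empty trip-distance cache
#'
#' @return An environment used by [trip_distance()] to memoise distances per
#'   unordered station pair.
#' @export
new_trip_cache <- function() new.env(parent = emptyenv())

station_key <- function(station) {
  paste(station$installation_name, station$station_name, sep = "\r")
}

# Over-water distance between two coordinate pairs under the standard rule.
over_water_distance <- function(lon1, lat1, lon2, lat2, surface) {
  if (!crosses_land(lon1, lat1, lon2, lat2, surface)) {
    list(distance_m = great_circle_distance(lon1, lat1, lon2, lat2),
         method = "straight")
  } else {
    d <- tryCatch(least_cost_distance(lon1, lat1, lon2, lat2, surface),
                  error = function(e) Inf)
    list(distance_m = d, method = "least_cost")
  }
}

#' Distance between two stations for movement QC
#'
#' Applies the trip-distance rule (straight over water, least-cost around
#' land, composite routing via the nearest coastline point for river
#' stations) and memoises the result per unordered station pair.
#'
#' @param a,b Station records: lists or one-row data frames with
#'   `installation_name`, `station_name`, `longitude`, `latitude` and
#'   `habitat` (`"ocean"` or `"river"`; missing habitat is treated as ocean).
#' @param surface A [build_cost_surface()] object.
#' @param cache Optional cache from [new_trip_cache()].
#' @return A list with `from_station`, `to_station`, `distance_m` and
#'   `method` (`"straight"`, `"least_cost"` or `"river_composite"`).
#'   `distance_m` is `Inf` when no over-water path exists.
#' @export
trip_distance <- function(a, b, surface, cache = NULL) {
  ka <- station_key(a); kb <- station_key(b)
  key <- paste(sort(c(ka, kb)), collapse = "\n")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])

  habitat_of <- function(s) {
    h <- s$habitat
    if (is.null(h) || is.na(h) || !nzchar(h)) "ocean" else h
  }
  ha <- habitat_of(a); hb <- habitat_of(b)

  if (ka == kb) {
    res <- list(distance_m = 0, method = "straight")
  } else if (ha == "river" && hb == "river" &&
             identical(a$installation_name, b$installation_name)) {
    res <- list(
      distance_m = great_circle_distance(a$longitude, a$latitude,
                                         b$longitude, b$latitude),
      method = "straight"
    )
  } else if (ha == "river" || hb == "river") {
    total <- 0
    pa <- list(lon = a$longitude, lat = a$latitude)
    pb <- list(lon = b$longitude, lat = b$latitude)
    if (ha == "river") {
      cp <- nearest_coast_point(pa$lon, pa$lat, surface)
      total <- total + cp$distance_m
      pa <- list(lon = cp$lon, lat = cp$lat)
    }
    if (hb == "river") {
      cp <- nearest_coast_point(pb$lon, pb$lat, surface)
      total <- total + cp$distance_m
      pb <- list(lon = cp$lon, lat = cp$lat)
    }
    ow <- over_water_distance(pa$lon, pa$lat, pb$lon, pb$lat, surface)
    res <- list(distance_m = total + ow$distance_m, method = "river_composite")
  } else {
    res <- over_water_distance(a$longitude, a$latitude,
                               b$longitude, b$latitude, surface)
  }

  out <- list(
    from_station = ka, to_station = kb,
    distance_m = res$distance_m, method = res$method
  )
  if (!is.null(cache)) cache[[key]] <- out
  out
}
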