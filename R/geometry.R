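# Spherical geometry helpers and lightweight polygon handling.
#
# All "straight-line" distances in the package are great-circle (haversine)
# distances on a sphere of radius 6,371 km. Polygons are stored as plain
# lists of closed rings (two-column lon/lat matrices, WGS84); holes are not
# supported -- the expert-distribution and land geometries handled here are
# simple outer rings.

EARTH_RADIUS_M <- 6371000

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6,371,000 m. Inputs are recycled
#' to a common length, so the function works on pairs of points or on whole
#' tracks at once.
#'
#' @param lon1,lat1 Coordinates of the first point(s), decimal degrees WGS84.
#' @param lon2,lat2 Coordinates of the second point(s).
#' @return Distance(s) in metres.
#' @examples
#' great_circle_distance(0, 0, 1, 0) # ~111,195 m (one degree at the equator)
#' @export
great_circle_distance <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  stopifnot(all(abs(p1[, 2]) <= 90), all(abs(p2[, 2]) <= 90))
  as.numeric(geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M))
}

# Close a ring if its first and last vertices differ.
close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

# Axis-aligned rectangle ring (lon/lat), counter-clockwise, closed.
rect_ring <- function(xmin, ymin, xmax, ymax) {
  close_ring(cbind(
    lon = c(xmin, xmax, xmax, xmin),
    lat = c(ymin, ymin, ymax, ymax)
  ))
}

#' Point-in-polygon test (ray casting)
#'
#' Tests whether points fall inside any ring of a polygon set. Points on an
#' edge may be classified either way at machine precision; the QC tests that
#' rely on this function combine it with a geodesic buffer, so edge cases are
#' absorbed by the buffer.
#'
#' @param lon,lat Point coordinates (vectorised).
#' @param polygons A list of closed rings (two-column lon/lat matrices).
#' @return Logical vector, `TRUE` where the point is inside any ring.
#' @export
point_in_polygons <- function(lon, lat, polygons) {
  if (length(polygons) == 0) return(rep(FALSE, length(lon)))
  inside <- rep(FALSE, length(lon))
  for (ring in polygons) {
    ring <- close_ring(ring)
    rx <- ring[, 1]; ry <- ring[, 2]
    nv <- length(rx) - 1L
    in_ring <- rep(FALSE, length(lon))
    for (i in seq_len(nv)) {
      x1 <- rx[i]; y1 <- ry[i]; x2 <- rx[i + 1L]; y2 <- ry[i + 1L]
      crosses <- ((y1 > lat) != (y2 > lat))
      if (any(crosses)) {
        xint <- x1 + (lat - y1) * (x2 - x1) / (y2 - y1)
        in_ring <- xor(in_ring, crosses & (lon < xint))
      }
    }
    inside <- inside | in_ring
  }
  inside
}

# Minimum great-circle distance (m) from each point to the boundary of a
# polygon set. Uses geosphere's point-to-polyline machinery per ring.
dist_to_polygons_m <- function(lon, lat, polygons) {
  stopifnot(length(polygons) > 0)
  pts <- cbind(lon, lat)
  d <- rep(Inf, length(lon))
  for (ring in polygons) {
    ring <- close_ring(ring)
    dr <- geosphere::dist2Line(pts, ring)[, "distance"]
    d <- pmin(d, dr)
  }
  d
}

#' Test points against a geodesically buffered polygon set
#'
#' A point passes when it lies inside any polygon ring or within
#' `buffer_m` metres of any ring boundary.
#'
#' @param lon,lat Point coordinates (vectorised).
#' @param polygons List of closed lon/lat rings.
#' @param buffer_m Buffer distance in metres (default 500 km, the
#'   species-distribution allowance for range shifts and mapping error).
#' @return Logical vector.
#' @export
within_buffered_polygons <- function(lon, lat, polygons, buffer_m = 5e5) {
  inside <- point_in_polygons(lon, lat, polygons)
  if (all(inside) || length(polygons) == 0) return(inside)
  out <- which(!inside)
  inside[out] <- dist_to_polygons_m(lon[out], lat[out], polygons) <= buffer_m
  inside
}

#' Read polygons from a GeoJSON file
#'
#' Supports `Polygon` and `MultiPolygon` geometries (in a Feature,
#' FeatureCollection, or bare geometry). Only outer rings are kept; interior
#' rings (holes) are ignored.
#'
#' @param path Path to a GeoJSON file (WGS84 coordinates).
#' @return A list of closed lon/lat ring matrices.
#' @export
read_geojson_polygons <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  rings <- list()
  add_geom <- function(geom) {
    if (is.null(geom)) return()
    type <- geom$type
    coords_ring <- function(rg) {
      m <- do.call(rbind, lapply(rg, function(p) c(p[[1]], p[[2]])))
      colnames(m) <- c("lon", "lat")
      close_ring(m)
    }
    if (identical(type, "Polygon")) {
      rings[[length(rings) + 1L]] <<- coords_ring(geom$coordinates[[1]])
    } else if (identical(type, "MultiPolygon")) {
      for (poly in geom$coordinates) {
        rings[[length(rings) + 1L]] <<- coords_ring(poly[[1]])
      }
    } else {
      stop("unsupported GeoJSON geometry type: ", type)
    }
  }
  if (identical(g$type, "FeatureCollection")) {
    for (f in g$features) add_geom(f$geometry)
  } else if (identical(g$type, "Feature")) {
    add_geom(g$geometry)
  } else {
    add_geom(g)
  }
  for (ring in rings) {
    if (any(!is.finite(ring))) stop("invalid polygon geometry in ", path)
  }
  rings
}

#' Write polygons to a GeoJSON file
#'
#' @param polygons List of closed lon/lat ring matrices (one Polygon feature
#'   each).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polygons, path) {
  features <- lapply(polygons, function(ring) {
    ring <- close_ring(ring)
    coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    list(
      type = "Feature",
      properties = stats::setNames(list(), character(0)),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
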