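# Rasterised land/water cost surface.
#
# The surface is a regular lon/lat grid ("north up": row 1 is the
# northernmost row). A cell is land when its centre falls inside any land
# polygon. Water cells form an implicit weighted graph (16-neighbour
# connectivity by default, i.e. the 8 adjacent cells plus knight's moves,
# which reduces the grid-path inflation of shortest paths); edge weights are
# great-circle distances between cell centres. The edge list is built lazily
# and cached inside the surface, as shortest-path queries are the expensive
# step of the QC run.

# Neighbour offsets (row, col), forward half only so each undirected edge is
# generated once.
offsets_for <- function(directions) {
  eight <- rbind(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  knight <- rbind(c(1L, -2L), c(1L, 2L), c(2L, -1L), c(2L, 1L))
  switch(as.character(directions),
    "4" = rbind(c(0L, 1L), c(1L, 0L)),
    "8" = eight,
    "16" = rbind(eight, knight),
    stop("directions must be 4, 8 or 16")
  )
}

#' Build a rasterised land/water cost surface
#'
#' Rasterises land polygons over a bounding box: every cell whose centre lies
#' inside a land polygon is land, all other cells are water. Water cells are
#' implicitly connected into a weighted graph used for over-water
#' shortest-path distances.
#'
#' @param land_polygons List of closed lon/lat rings (possibly empty for an
#'   all-water surface), e.g. from [read_geojson_polygons()].
#' @param resolution Cell size in decimal degrees (> 0). Default 0.05.
#' @param bounds Named numeric vector `c(xmin, xmax, ymin, ymax)` in decimal
#'   degrees.
#' @param directions Water-graph connectivity: 4, 8 or 16 (default)
#'   neighbours.
#' @return A `cost_surface` object.
#' @export
build_cost_surface <- function(land_polygons, resolution = 0.05, bounds,
                               directions = 16) {
  stopifnot(resolution > 0, length(bounds) == 4)
  bounds <- as.numeric(bounds[c("xmin", "xmax", "ymin", "ymax")])
  if (any(is.na(bounds))) {
    stop("bounds must be a named vector with xmin, xmax, ymin, ymax")
  }
  xmin <- bounds[1]; xmax <- bounds[2]; ymin <- bounds[3]; ymax <- bounds[4]
  stopifnot(xmax > xmin, ymax > ymin)
  ncol <- max(1L, as.integer(round((xmax - xmin) / resolution)))
  nrow <- max(1L, as.integer(round((ymax - ymin) / resolution)))
  lon <- xmin + (seq_len(ncol) - 0.5) * resolution
  lat <- ymax - (seq_len(nrow) - 0.5) * resolution # row 1 = north
  centres_lon <- rep(lon, times = nrow)
  centres_lat <- rep(lat, each = ncol)
  land_vec <- point_in_polygons(centres_lon, centres_lat, land_polygons)
  land <- matrix(land_vec, nrow = nrow, ncol = ncol, byrow = TRUE)
  if (all(land)) stop("no water cells: bounds are entirely land")
  surface <- structure(
    list(
      land = land, nrow = nrow, ncol = ncol,
      xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
      resolution = resolution,
      lon = lon, lat = lat,
      directions = as.integer(directions),
      cache = new.env(parent = emptyenv())
    ),
    class = "cost_surface"
  )
  surface
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf(
    "<cost_surface> %d x %d cells at %g deg (%.6g%% land), %d-neighbour graph\n",
    x$nrow, x$ncol, x$resolution, 100 * mean(x$land), x$directions
  ))
  cat(sprintf(
    "  extent: lon [%g, %g], lat [%g, %g]\n", x$xmin, x$xmax, x$ymin, x$ymax
  ))
  invisible(x)
}

n_land_cells <- function(surface) sum(surface$land)

# Cell index (1-based, row-major) from coordinates; NA outside bounds.
cell_from_xy <- function(surface, lon, lat) {
  col <- floor((lon - surface$xmin) / surface$resolution) + 1
  row <- floor((surface$ymax - lat) / surface$resolution) + 1
  # points exactly on the max edge belong to the last cell
  col[lon == surface$xmax] <- surface$ncol
  row[lat == surface$ymin] <- surface$nrow
  bad <- col < 1 | col > surface$ncol | row < 1 | row > surface$nrow |
    is.na(lon) | is.na(lat)
  cell <- (as.integer(row) - 1L) * surface$ncol + as.integer(col)
  cell[bad] <- NA_integer_
  cell
}

cell_rowcol <- function(surface, cell) {
  row <- ((cell - 1L) %/% surface$ncol) + 1L
  col <- ((cell - 1L) %% surface$ncol) + 1L
  cbind(row = row, col = col)
}

# Cell-centre coordinates.
cell_xy <- function(surface, cell) {
  rc <- cell_rowcol(surface, cell)
  cbind(lon = surface$lon[rc[, "col"]], lat = surface$lat[rc[, "row"]])
}

is_land_cell <- function(surface, cell) {
  rc <- cell_rowcol(surface, cell)
  surface$land[cbind(rc[, "row"], rc[, "col"])]
}

#' Interpolate positions along a trip
#'
#' Generates `n_points` positions, endpoints included, linearly interpolated
#' in lon/lat between two points. This is the sampling used by the
#' land-crossing test (default 200 positions per trip).
#'
#' @param lon1,lat1,lon2,lat2 Trip endpoints, decimal degrees.
#' @param n_points Number of positions to generate (>= 2; default 200).
#' @return A two-column matrix (lon, lat) with `n_points` rows.
#' @export
interpolate_trip <- function(lon1, lat1, lon2, lat2, n_points = 200) {
  stopifnot(n_points >= 2)
  f <- seq(0, 1, length.out = n_points)
  cbind(lon = lon1 + f * (lon2 - lon1), lat = lat1 + f * (lat2 - lat1))
}

#' Does the straight line between two points cross land?
#'
#' Samples `n_points` linearly interpolated positions (endpoints included)
#' between the two points and reports whether any falls on a land cell.
#'
#' @inheritParams interpolate_trip
#' @param surface A [build_cost_surface()] object.
#' @return `TRUE` if any sampled position is on land.
#' @export
crosses_land <- function(lon1, lat1, lon2, lat2, surface, n_points = 200) {
  pts <- interpolate_trip(lon1, lat1, lon2, lat2, n_points)
  cells <- cell_from_xy(surface, pts[, "lon"], pts[, "lat"])
  if (anyNA(cells)) stop("trip leaves the cost-surface bounds")
  any(is_land_cell(surface, cells))
}

water_cells <- function(surface) {
  which(t(!surface$land)) # row-major cell ids
}

#' Snap a point to its nearest water cell
#'
#' Returns the point's own cell when it is water; otherwise the water cell
#' whose centre is nearest by great-circle distance, with ties broken by
#' lowest (row, column).
#'
#' @param lon,lat Point coordinates (scalar).
#' @param surface A `cost_surface`.
#' @return The water cell index (1-based, row-major).
#' @export
snap_to_water <- function(lon, lat, surface) {
  cell <- cell_from_xy(surface, lon, lat)
  if (is.na(cell)) stop("point outside the cost-surface bounds")
  if (!is_land_cell(surface, cell)) return(cell)
  ww <- water_cells(surface)
  xy <- cell_xy(surface, ww)
  d <- great_circle_distance(lon, lat, xy[, "lon"], xy[, "lat"])
  # deterministic tie-break: water_cells() is already in (row, col) order
  ww[which.min(d)]
}

# Water cells with at least one land 8-neighbour.
coastal_cells <- function(surface) {
  key <- "coastal_cells"
  if (!is.null(surface$cache[[key]])) return(surface$cache[[key]])
  land <- surface$land
  nr <- surface$nrow; nc <- surface$ncol
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- land
  near_land <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    near_land <- near_land | pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  cells <- which(t(!land & near_land))
  surface$cache[[key]] <- cells
  cells
}

#' Nearest coastline point to a position
#'
#' Finds the coastal water cell (a water cell adjacent to land) whose centre
#' is nearest to the point by great-circle distance; ties broken by lowest
#' (row, column). Used to route river detections to the open coast.
#'
#' @param lon,lat Point coordinates (scalar).
#' @param surface A `cost_surface`.
#' @return A list with `lon`, `lat`, `cell` and `distance_m`.
#' @export
nearest_coast_point <- function(lon, lat, surface) {
  cc <- coastal_cells(surface)
  if (length(cc) == 0) stop("surface has no coastal cells (all water)")
  xy <- cell_xy(surface, cc)
  d <- great_circle_distance(lon, lat, xy[, "lon"], xy[, "lat"])
  i <- which.min(d)
  list(lon = unname(xy[i, "lon"]), lat = unname(xy[i, "lat"]),
       cell = cc[i], distance_m = unname(d[i]))
}

# Undirected water-graph edge list with great-circle weights, built once and
# cached. Nodes are raw cell ids; only water-water edges are kept.
surface_edges <- function(surface) {
  key <- "edges"
  if (!is.null(surface$cache[[key]])) return(surface$cache[[key]])
  nr <- surface$nrow; nc <- surface$ncol
  water <- t(!surface$land) # water[col, row] indexed by cell id
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offsets_for(surface$directions)))) {
    off <- offsets_for(surface$directions)[k, ]
    rows <- seq_len(nr); cols <- seq_len(nc)
    r2 <- rows + off[1]; c2 <- cols + off[2]
    rok <- rows[r2 >= 1 & r2 <= nr]; cok <- cols[c2 >= 1 & c2 <= nc]
    if (length(rok) == 0 || length(cok) == 0) next
    r1g <- rep(rok, times = length(cok)); c1g <- rep(cok, each = length(rok))
    r2g <- r1g + off[1]; c2g <- c1g + off[2]
    a <- (r1g - 1L) * nc + c1g
    b <- (r2g - 1L) * nc + c2g
    keep <- water[a] & water[b]
    from <- c(from, a[keep]); to <- c(to, b[keep])
  }
  xy1 <- cell_xy(surface, from); xy2 <- cell_xy(surface, to)
  w <- great_circle_distance(xy1[, "lon"], xy1[, "lat"],
                             xy2[, "lon"], xy2[, "lat"])
  edges <- list(from = from, to = to, weight = w)
  surface$cache[[key]] <- edges
  edges
}

# Map raw cell ids to compact water-node indices (1..n_water).
water_node_index <- function(surface) {
  key <- "node_index"
  if (!is.null(surface$cache[[key]])) return(surface$cache[[key]])
  ww <- water_cells(surface)
  idx <- integer(surface$nrow * surface$ncol)
  idx[ww] <- seq_along(ww)
  res <- list(cells = ww, index = idx)
  surface$cache[[key]] <- res
  res
}

#' Least-cost over-water distance between two points
#'
#' Snaps both points to water cells ([snap_to_water()]) and returns the
#' length of the shortest path through the water-cell graph (Dijkstra), with
#' edge weights equal to the great-circle distance between neighbouring cell
#' centres. The result is never less than the great-circle distance between
#' the snapped cell centres, and exceeds it by at most the grid-metric
#' inflation of the chosen connectivity (about 8% for 16 neighbours).
#'
#' @param lon1,lat1,lon2,lat2 Point coordinates (scalar).
#' @param surface A `cost_surface`.
#' @return Distance in metres.
#' @section Errors: If the two snapped cells lie in disconnected water bodies
#'   the function throws an "unreachable" error; [trip_distance()] converts
#'   this into an infinite distance so the distance QC test fails.
#' @export
least_cost_distance <- function(lon1, lat1, lon2, lat2, surface) {
  src <- snap_to_water(lon1, lat1, surface)
  dst <- snap_to_water(lon2, lat2, surface)
  if (src == dst) return(0)
  ni <- water_node_index(surface)
  edges <- surface_edges(surface)
  d <- dijkstra_source_dist(
    length(ni$cells),
    ni$index[edges$from], ni$index[edges$to], edges$weight,
    ni$index[src]
  )
  out <- d[ni$index[dst]]
  if (!is.finite(out)) {
    stop("unreachable: no over-water path between the two points")
  }
  out
}
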