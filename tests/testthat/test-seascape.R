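test_that("rasterisation classifies cell centres against land polygons", {
  # empty polygon set: all water
  s0 <- water_surface(c(xmin = 0, xmax = 2, ymin = 0, ymax = 2), 0.5)
  expect_equal(sum(s0$land), 0)
  # bounds entirely land: degenerate
  expect_error(
    build_cost_surface(list(tagqc:::rect_ring(-1, -1, 3, 3)), 0.5,
                       c(xmin = 0, xmax = 2, ymin = 0, ymax = 2)),
    "no water"
  )
  # 1x1 degree island centred in a 10x10 degree box at 0.1 degrees:
  # exactly 100 cell centres fall inside the square
  island <- island_surface()
  expect_equal(sum(island$land), 100)
  # rasterising twice yields identical grids
  expect_identical(island$land, island_surface()$land)
})

test_that("land-crossing test interpolates inclusive endpoints", {
  island <- island_surface()
  expect_equal(nrow(interpolate_trip(141, -35, 149, -35)), 200)
  pts <- interpolate_trip(141, -35, 149, -35, 5)
  expect_equal(pts[, "lon"], c(141, 143, 145, 147, 149))
  expect_false(crosses_land(141, -39, 149, -39, island)) # south of island
  expect_true(crosses_land(141, -35, 149, -35, island))  # bisects island
  expect_false(crosses_land(141, -39, 141, -39, island)) # degenerate a == b
  expect_error(crosses_land(141, -35, 160, -35, island), "bounds")
})

test_that("points snap to the nearest water cell with a deterministic tie-break", {
  island <- island_surface()
  # open-water point: its own cell
  own <- tagqc:::cell_from_xy(island, 141.05, -38.95)
  expect_equal(snap_to_water(141.05, -38.95, island), own)
  # point on the island: nearest water cell by brute force
  snapped <- snap_to_water(145.01, -34.99, island)
  ww <- tagqc:::water_cells(island)
  xy <- tagqc:::cell_xy(island, ww)
  d <- great_circle_distance(145.01, -34.99, xy[, "lon"], xy[, "lat"])
  expect_false(tagqc:::is_land_cell(island, snapped))
  expect_equal(
    great_circle_distance(
      145.01, -34.99,
      tagqc:::cell_xy(island, snapped)[, "lon"],
      tagqc:::cell_xy(island, snapped)[, "lat"]
    ),
    min(d)
  )
  # equidistant candidates resolve to the lowest (row, column):
  # 1 x 3 grid, land in the middle, point at the exact centre
  tiny <- build_cost_surface(
    list(tagqc:::rect_ring(0.1, 0, 0.2, 0.1)), 0.1,
    c(xmin = 0, xmax = 0.3, ymin = 0, ymax = 0.1)
  )
  expect_equal(snap_to_water(0.15, 0.05, tiny), 1L)
})

test_that("nearest coast point is the closest water cell adjacent to land", {
  bay <- make_seascape("bay")$surface
  p <- c(148.2, -35) # inside the bay
  res <- nearest_coast_point(p[1], p[2], bay)
  cc <- tagqc:::coastal_cells(bay)
  xy <- tagqc:::cell_xy(bay, cc)
  d <- great_circle_distance(p[1], p[2], xy[, "lon"], xy[, "lat"])
  expect_equal(res$cell, cc[which.min(d)])
  expect_equal(res$distance_m, min(d))
  # a coastal cell centre maps to itself at distance zero
  self <- tagqc:::cell_xy(bay, cc[1])
  res2 <- nearest_coast_point(self[, "lon"], self[, "lat"], bay)
  expect_equal(res2$cell, cc[1])
  expect_equal(res2$distance_m, 0)
  # all-water grid has no coastline
  expect_error(nearest_coast_point(115, -32, water_surface()), "coastal")
})

test_that("least-cost distance matches an independent Dijkstra oracle", {
  skip_if_not_installed("igraph")
  island <- island_surface() # 100 x 100 cells
  edges <- tagqc:::surface_edges(island)
  ni <- tagqc:::water_node_index(island)
  g <- igraph::make_empty_graph(n = length(ni$cells), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ni$index[edges$from], ni$index[edges$to]))
  igraph::E(g)$weight <- edges$weight

  oracle <- function(lon1, lat1, lon2, lat2) {
    src <- ni$index[snap_to_water(lon1, lat1, island)]
    dst <- ni$index[snap_to_water(lon2, lat2, island)]
    as.numeric(igraph::distances(g, v = src, to = dst,
                                 algorithm = "dijkstra"))
  }
  pairs <- list(
    c(141.05, -35.05, 148.95, -35.05), # opposite sides of the island
    c(141.05, -30.05, 148.95, -39.95), # diagonal
    c(144.05, -34.05, 146.05, -36.05)  # hugging the island corner
  )
  for (p in pairs) {
    expect_equal(least_cost_distance(p[1], p[2], p[3], p[4], island),
                 oracle(p[1], p[2], p[3], p[4]), tolerance = 1e-9)
  }
  # both points in the same water cell
  expect_equal(least_cost_distance(141.01, -35.01, 141.04, -35.04, island), 0)
})

test_that("least-cost never beats great-circle and stays within grid inflation", {
  island <- island_surface()
  ww <- tagqc:::water_cells(island)
  set.seed(7)
  idx <- matrix(sample(ww, 40, replace = TRUE), ncol = 2)
  for (k in seq_len(nrow(idx))) {
    a <- tagqc:::cell_xy(island, idx[k, 1])
    b <- tagqc:::cell_xy(island, idx[k, 2])
    lcd <- least_cost_distance(a[, "lon"], a[, "lat"],
                               b[, "lon"], b[, "lat"], island)
    hav <- great_circle_distance(a[, "lon"], a[, "lat"],
                                 b[, "lon"], b[, "lat"])
    expect_gte(lcd, hav - 1e-6)
    if (!crosses_land(a[, "lon"], a[, "lat"], b[, "lon"], b[, "lat"],
                      island)) {
      expect_lte(lcd, hav * 1.085) # 16-neighbour grid-metric inflation bound
    }
  }
})

test_that("refining the raster cannot lengthen over-water routes materially", {
  coarse <- island_surface(0.1)
  fine <- island_surface(0.05)
  p <- c(141.05, -35.05, 148.95, -35.05)
  d_coarse <- least_cost_distance(p[1], p[2], p[3], p[4], coarse)
  d_fine <- least_cost_distance(p[1], p[2], p[3], p[4], fine)
  hav <- great_circle_distance(p[1], p[2], p[3], p[4])
  diag_w <- sqrt(2) * 0.1 * pi / 180 * 6371000
  expect_gte(d_fine, hav)
  expect_lte(d_fine, d_coarse + 2 * diag_w)
})

test_that("disconnected water bodies are unreachable", {
  # a 1-degree (10-cell) land wall splits the box into two basins
  wall <- build_cost_surface(
    list(tagqc:::rect_ring(144.5, -41, 145.5, -29)), 0.1,
    c(xmin = 140, xmax = 150, ymin = -40, ymax = -30)
  )
  expect_error(least_cost_distance(141, -35, 149, -35, wall), "unreachable")
})
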