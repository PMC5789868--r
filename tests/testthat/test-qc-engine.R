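test_that("false-detection algorithm applies the interval-ratio rule per installation", {
  cfg <- qc_config()
  t0 <- UTC("2012-01-15 00:00:00")
  # a single detection at an installation is suspect
  expect_equal(fda_test(fake_detections(t0), cfg), 2L)
  # five detections 10 minutes apart: 4 short, 0 long intervals -> pass
  expect_equal(fda_test(fake_detections(t0 + 600 * (0:4)), cfg), rep(1L, 5))
  # three detections 24 h apart: 0 short, 2 long -> fail
  expect_equal(fda_test(fake_detections(t0 + 86400 * (0:2)), cfg), rep(2L, 3))
  # intervals between 30 min and 12 h count for neither side -> pass (0 > 0 is false)
  expect_equal(fda_test(fake_detections(t0 + 3600 * (0:2)), cfg), rep(1L, 3))
  # groups are independent: a singleton at Y does not taint X
  det <- rbind(
    fake_detections(t0 + 600 * (0:3), installation = "X"),
    fake_detections(t0 + 86400, installation = "Y", station = "S9")
  )
  det <- det[order(det$detection_timestamp), ]
  expect_equal(fda_test(det, cfg)[det$installation_name == "X"], rep(1L, 4))
  expect_equal(fda_test(det, cfg)[det$installation_name == "Y"], 2L)
})

test_that("all detections of a tag at one installation share the FDA flag", {
  cfg <- qc_config()
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(2:30, 1)
    ts <- UTC("2012-01-15 00:00:00") +
      cumsum(sample(c(60, 900, 7200, 13 * 3600), n, TRUE))
    det <- fake_detections(ts, installation = sample(c("A", "B"), n, TRUE))
    det <- det[order(det$detection_timestamp), ]
    f <- fda_test(det, cfg)
    for (inst in unique(det$installation_name)) {
      expect_equal(length(unique(f[det$installation_name == inst])), 1)
    }
  }
})

test_that("neighbour metrics give distances, speeds and the 1 s simultaneity rule", {
  surface <- water_surface()
  st <- fake_stations(c(115, 115, 115.5), c(-32, -31, -32),
                      c("S1", "S2", "S3"))
  t0 <- UTC("2012-01-15 00:00:00")
  # consecutive detections at the same station: zero distance and speed
  det <- fake_detections(t0 + c(0, 600), station = "S1")
  m <- neighbour_metrics(det, st, surface)
  expect_equal(m$dist_next[1], 0)
  expect_equal(m$vel_next[1], 0)
  expect_true(is.na(m$dist_prev[1]) && is.na(m$dist_next[2]))
  # one degree of latitude in one hour: ~30.9 m/s
  det <- fake_detections(t0 + c(0, 3600), station = c("S1", "S2"),
                         lat = c(-32, -31))
  m <- neighbour_metrics(det, st, surface)
  expect_equal(m$vel_next[1], great_circle_distance(115, -32, 115, -31) / 3600,
               tolerance = 1e-9)
  expect_equal(m$vel_next[1], 30.887, tolerance = 1e-3)
  # simultaneous detections at two receivers: interval floored at 1 s
  det <- fake_detections(c(t0, t0), station = c("S1", "S3"),
                         lon = c(115, 115.5))
  m <- neighbour_metrics(det, st, surface)
  expect_equal(m$vel_next[1], great_circle_distance(115, -32, 115.5, -32) / 1)
  # unknown stations are reported by name
  det <- fake_detections(t0 + c(0, 60), station = c("S1", "GHOST"))
  expect_error(neighbour_metrics(det, st, surface), "GHOST")
})

test_that("distance and velocity tests require both neighbours beyond threshold", {
  cfg <- qc_config()
  km <- 1e3
  expect_equal(distance_test(fake_metrics(1200 * km, 1100 * km), cfg), 2L)
  expect_equal(distance_test(fake_metrics(1200 * km, 5 * km), cfg), 1L)
  expect_equal(distance_test(fake_metrics(NA, 1200 * km), cfg), 2L) # endpoint
  expect_equal(distance_test(fake_metrics(NA, 5 * km), cfg), 1L)
  expect_equal(distance_test(fake_metrics(NA, NA), cfg), 1L) # sole detection
  expect_equal(distance_test(fake_metrics(Inf, Inf), cfg), 2L) # unreachable
  # boundary: exactly 1,000 km passes ("greater than" is strict)
  expect_equal(distance_test(fake_metrics(1000 * km, 1000 * km), cfg), 1L)

  expect_equal(velocity_test(fake_metrics(vel_prev = 12, vel_next = 15), cfg), 2L)
  expect_equal(velocity_test(fake_metrics(vel_prev = 12, vel_next = 0.5), cfg), 1L)
  expect_equal(velocity_test(fake_metrics(vel_prev = 10, vel_next = 10), cfg), 1L)
  expect_equal(velocity_test(fake_metrics(vel_prev = NA, vel_next = 10.01), cfg), 2L)
})

test_that("plausible interval/distance combinations cannot fail distance or velocity", {
  cfg <- qc_config()
  set.seed(31)
  for (rep in 1:50) {
    d <- runif(2, 0, cfg$distance_threshold_m)
    dt <- runif(2, cfg$distance_threshold_m / cfg$velocity_threshold_ms, 4e5)
    m <- fake_metrics(d[1], d[2], d[1] / dt[1], d[2] / dt[2])
    expect_equal(distance_test(m, cfg), 1L)
    expect_equal(velocity_test(m, cfg), 1L)
  }
})

test_that("distribution test buffers polygons and reports unavailable distributions", {
  sq <- list(tagqc:::rect_ring(110, -40, 120, -30))
  det <- fake_detections(UTC("2012-01-15 00:00:00") + 0:2,
                         lon = c(115, 138, 121), lat = c(-35, -35, -35))
  flags <- distribution_test(det, sq, buffer_m = 5e5)
  expect_equal(flags[1], 1L) # inside the raw polygon
  expect_equal(flags[2], 2L) # ~1,600 km east of the boundary
  expect_equal(flags[3], 1L) # ~90 km east: inside the 500 km buffer
  expect_equal(distribution_test(det, NULL), rep(3L, 3)) # not performed
})

test_that("distance-from-release uses an inclusive 500 km radius", {
  t0 <- UTC("2012-01-15 00:00:00")
  dep <- fake_deployment(lon = 115, lat = -32)
  at_release <- fake_detections(t0, lon = 115, lat = -32)
  expect_equal(distance_release_test(at_release, dep), 1L)
  # points on the same meridian: metres per degree of latitude is exact
  m_per_deg <- 6371000 * pi / 180
  near <- fake_detections(t0, lon = 115, lat = -32 + 499e3 / m_per_deg)
  far <- fake_detections(t0, lon = 115, lat = -32 + 501e3 / m_per_deg)
  expect_equal(distance_release_test(near, dep), 1L)
  expect_equal(distance_release_test(far, dep), 2L)
  # the radius is inclusive: a distance exactly at the threshold passes
  at <- fake_detections(t0, lon = 115, lat = -31)
  exact <- great_circle_distance(115, -32, 115, -31)
  expect_equal(distance_release_test(at, dep, radius_m = exact), 1L)
  # missing release coordinates: flag 2 with a warning
  dep_na <- fake_deployment(lon = NA_real_, lat = NA_real_)
  expect_warning(f <- distance_release_test(at_release, dep_na), "release")
  expect_equal(f, 2L)
})

test_that("release-date test honours the grace window", {
  dep <- fake_deployment(datetime = UTC("2012-01-10 00:00:00"))
  t_rel <- UTC("2012-01-10 00:00:00")
  det <- fake_detections(c(t_rel - 10 * 86400, t_rel - 3600, t_rel + 3600))
  expect_equal(release_date_test(det, dep, grace_s = 86400), c(2L, 1L, 1L))
})

test_that("release-location combines distribution and first-detection checks", {
  sq <- list(tagqc:::rect_ring(110, -40, 120, -30))
  first_near <- fake_detections(UTC("2012-01-15 00:00:00"), lon = 115.1,
                                lat = -32)
  first_far <- fake_detections(UTC("2012-01-15 00:00:00"), lon = 150,
                               lat = -15)
  inside <- fake_deployment(lon = 115, lat = -32)
  outside <- fake_deployment(lon = 151, lat = -15.1)
  # inside distribution, first detection 2,000+ km away: still passes (or-rule)
  expect_equal(release_location_test(inside, first_far, sq), 1L)
  # outside distribution but close to the first detection: passes
  expect_equal(release_location_test(outside, first_far, sq), 1L)
  # both evaluable checks fail
  expect_equal(release_location_test(outside, first_near, sq), 2L)
  # no distribution and no detections: not performed
  expect_equal(release_location_test(inside, NULL, NULL), 3L)
  # one evaluable check failing is enough to fail
  expect_equal(release_location_test(outside, NULL, sq), 2L)
})

test_that("composite flag reproduces the published mapping over all combinations", {
  grid <- expand.grid(fda = 1:2, dist = 1:2, vel = 1:2, distr = 1:2,
                      rel = 1:2)
  got <- composite_flag(grid$fda, grid$dist, grid$vel, grid$distr, grid$rel)
  # independent mapping: count passes, then 5->1, 4->2, 3->3, <=2->4
  n_pass <- rowSums(grid == 1)
  expected <- c(4L, 4L, 4L, 3L, 2L, 1L)[pmin(n_pass, 5) + 1]
  expect_identical(got, expected)
  # "not performed" (3) counts as not passed
  expect_equal(composite_flag(1, 1, 1, 3, 1), 2L)
  expect_equal(composite_flag(1, 1, 1, 3, 2), 3L)
  # out-of-range components are rejected
  expect_error(composite_flag(1, 1, 1, 1, 3), "value set")
  expect_error(composite_flag(0, 1, 1, 1, 1), "value set")
})

test_that("composite flag is monotone in every component", {
  base <- expand.grid(fda = 1:2, dist = 1:2, vel = 1:2, distr = 1:3,
                      rel = 1:2)
  for (j in 1:5) {
    worse <- base
    worse[[j]] <- 2L
    keep <- base[[j]] == 1L
    expect_true(all(
      do.call(composite_flag, unname(as.list(worse[keep, ]))) >=
        do.call(composite_flag, unname(as.list(base[keep, ])))
    ))
  }
})

test_that("qc_deployment flags an injected pre-release detection and logs counts", {
  surface <- water_surface()
  st <- fake_stations(c(115, 115.01), c(-32, -32), c("S1", "S2"))
  dep <- fake_deployment(datetime = UTC("2012-01-10 00:00:00"),
                         species = "Galeocerdo cuvier")
  t0 <- UTC("2012-01-15 00:00:00")
  det <- rbind(
    fake_detections(t0 + 600 * (0:4), station = "S1"),
    fake_detections(UTC("2011-12-25 00:00:00"), station = "S2")
  )
  distributions <- list("Galeocerdo cuvier" =
                          list(tagqc:::rect_ring(110, -40, 120, -30)))
  res <- qc_deployment(dep, det, st, surface, distributions)
  qc <- res$qc
  pre <- qc$detection_timestamp < UTC("2012-01-09 00:00:00")
  expect_equal(sum(pre), 1)
  expect_equal(qc$ReleaseDate_QC[pre], 2L)
  expect_equal(qc$ReleaseDate_QC[!pre], rep(1L, 5))
  expect_equal(res$log$fail_counts[["ReleaseDate_QC"]], 1)
  expect_equal(res$log$n_detections, 6)
  # the clean block passes everything
  expect_equal(qc$Detection_QC[!pre], rep(1L, 5))
  expect_equal(qc$ReleaseLocation_QC, rep(1L, 6))
})

test_that("missing distribution plus distant detections cap the composite at 3", {
  surface <- water_surface()
  st <- fake_stations(c(150, 150.01), c(-15, -15), c("S1", "S2"))
  # released at 115E, detections ~3,700 km away, species without distribution
  dep <- fake_deployment(lon = 115, lat = -32, species = "Sepia apama",
                         datetime = UTC("2012-01-10 00:00:00"))
  det <- fake_detections(UTC("2012-01-15 00:00:00") + 600 * (0:3),
                         station = "S1", lon = 150, lat = -15,
                         installation = "I1")
  res <- qc_deployment(dep, det, st, surface, distributions = list())
  expect_true(all(res$qc$DetectionDistribution_QC == 3L))
  expect_true(all(res$qc$DistanceRelease_QC == 2L))
  expect_true(all(res$qc$Detection_QC %in% 3:4))
})

test_that("qc output is invariant to input row order", {
  surface <- water_surface()
  st <- fake_stations(c(115, 115.01, 115.02), c(-32, -32, -32),
                      c("S1", "S2", "S3"))
  dep <- fake_deployment()
  t0 <- UTC("2012-01-15 00:00:00")
  det <- fake_detections(t0 + c(0, 60, 60, 180, 240),
                         station = c("S1", "S2", "S1", "S3", "S1"))
  res1 <- qc_deployment(dep, det, st, surface)
  set.seed(9)
  res2 <- qc_deployment(dep, det[sample(nrow(det)), ], st, surface)
  rownames(res2$qc) <- rownames(res1$qc) <- NULL
  expect_identical(res1$qc, res2$qc)
})
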