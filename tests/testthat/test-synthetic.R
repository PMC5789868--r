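test_that("analytic seascapes rasterise exactly as designed", {
  open <- make_seascape("open_water")
  expect_equal(sum(open$surface$land), 0)
  island <- make_seascape("square_island")
  expect_equal(sum(island$surface$land), 100)
  bay <- make_seascape("bay")
  # land block 3 x 6 degrees minus the 1.5 x 1 degree bay, at 0.1 degrees
  expect_equal(sum(bay$surface$land), 30 * 60 - 15 * 10)
  river <- make_seascape("river_and_coast")
  # land block 3 x 10 degrees minus the one-cell-wide, 2-degree-long channel
  expect_equal(sum(river$surface$land), 30 * 100 - 20)
  expect_error(make_seascape("atlantis"), "arg")
})

test_that("scenario definitions are validated", {
  expect_error(sim_scenario(), "seed")
  expect_error(sim_scenario(1, contamination = list(volcano = 3)), "unknown")
  expect_error(sim_scenario(1, contamination = list(teleport = -1)), ">= 0")
  # teleports need an extent larger than the distance threshold
  expect_error(sim_scenario(1, seascape = "bay",
                            contamination = list(teleport = 2)),
               "open_water")
})

test_that("river scenarios emit river-flagged stations in the registry", {
  scn <- sim_scenario(seed = 5, seascape = "river_and_coast",
                      n_deployments = 2, n_steps = 300,
                      contamination = list())
  sim <- simulate_scenario(scn)
  expect_true(any(sim$stations$habitat == "river"))
  riv <- sim$stations[sim$stations$habitat == "river", ]
  expect_equal(unique(riv$installation_name), "INST05")
})

test_that("scenarios are reproducible by seed and vary across seeds", {
  scn <- sim_scenario(seed = 8, n_deployments = 2, n_steps = 400,
                      contamination = list(pre_release = 2))
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  simulate_scenario(scn, out_dir = d1)
  simulate_scenario(scn, out_dir = d2)
  for (f in c("detections.csv", "tag_metadata.csv", "stations.csv",
              "truth_labels.csv", "land.geojson")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  scn2 <- sim_scenario(seed = 9, n_deployments = 2, n_steps = 400,
                       contamination = list(pre_release = 2))
  sim3 <- simulate_scenario(scn2, out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "detections.csv")),
                         readLines(file.path(d3, "detections.csv"))))
})

test_that("generated files round-trip through the package readers", {
  scn <- sim_scenario(seed = 13, n_deployments = 3, n_steps = 1500)
  dir <- tempfile()
  sim <- simulate_scenario(scn, out_dir = dir)
  expect_silent(det <- read_detections(file.path(dir, "detections.csv")))
  expect_equal(nrow(det), nrow(sim$detections))
  expect_silent(st <- read_stations(file.path(dir, "stations.csv")))
  expect_equal(nrow(st), nrow(sim$stations))
  deps <- read_tag_metadata(file.path(dir, "tag_metadata.csv"))
  expect_equal(nrow(deps), scn$n_deployments)
  expect_true(any(deps$dual_sensor_tag))
  # truth rows match the requested contamination
  truth <- utils::read.csv(file.path(dir, "truth_labels.csv"),
                           stringsAsFactors = FALSE)
  expect_equal(nrow(truth), sum(unlist(scn$contamination)))
  expect_equal(sort(unique(truth$label)),
               c("false_single_hit", "out_of_distribution", "pre_release",
                 "teleport"))
  # distributions written per species
  expect_equal(
    sort(list.files(file.path(dir, "distributions"))),
    sort(paste0(gsub(" ", "_", unique(scn$species)), ".geojson"))
  )
})

test_that("a clean confined scenario passes the whole QC battery", {
  scn <- sim_scenario(seed = 4, n_deployments = 3, n_steps = 1500,
                      contamination = list())
  sim <- simulate_scenario(scn)
  qc <- qc_simulated(sim)
  expect_gt(nrow(qc), 100)
  expect_true(all(qc$label == "clean"))
  expect_true(all(qc$Detection_QC == 1L))
})

test_that("a distribution far from all stations fails every detection", {
  scn <- sim_scenario(seed = 4, n_deployments = 2, n_steps = 500,
                      contamination = list())
  sim <- simulate_scenario(scn)
  # replace both species' distributions with a remote polygon
  far <- list(tagqc:::rect_ring(150, -15, 154, -11))
  sim$distributions <- lapply(sim$distributions, function(x) far)
  qc <- qc_simulated(sim)
  expect_true(all(qc$DetectionDistribution_QC == 2L))
})
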