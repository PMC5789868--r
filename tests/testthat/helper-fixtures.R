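# Shared fixtures: tiny analytic surfaces, detection frames and deployments
# built in code.

UTC <- function(x) as.POSIXct(x, tz = "UTC")

# All-water surface over an arbitrary box.
water_surface <- function(bounds = c(xmin = 110, xmax = 155,
                                     ymin = -45, ymax = -10),
                          resolution = 0.25, directions = 16) {
  build_cost_surface(list(), resolution, bounds, directions)
}

# The 10 x 10 degree square-island fixture (1 x 1 degree island at centre).
island_surface <- function(resolution = 0.1) {
  make_seascape("square_island", resolution = resolution)$surface
}

fake_detections <- function(ts, station = "S1", installation = "I1",
                            lon = 115, lat = -32, tid = "A69-9002-1",
                            receiver = "VR2W-1", sensor_value = NA_real_,
                            sensor_unit = NA_character_) {
  n <- length(ts)
  data.frame(
    transmitter_id = rep_len(tid, n),
    installation_name = rep_len(installation, n),
    station_name = rep_len(station, n),
    receiver_name = rep_len(receiver, n),
    detection_timestamp = ts,
    longitude = rep_len(lon, n),
    latitude = rep_len(lat, n),
    sensor_value = rep_len(sensor_value, n),
    sensor_unit = rep_len(sensor_unit, n),
    stringsAsFactors = FALSE
  )
}

fake_deployment <- function(tid = "A69-9002-1", tag = "T1", rel = "R1",
                            species = "Galeocerdo cuvier",
                            lon = 115, lat = -32,
                            datetime = UTC("2012-01-10 00:00:00"),
                            slope = NA_real_, intercept = NA_real_,
                            type = "pinger", unit = NA_character_) {
  d <- data.frame(
    tag_id = tag, release_id = rel, tag_project_name = "TEST",
    scientific_name = species, common_name = species,
    release_longitude = lon, release_latitude = lat,
    release_datetime = datetime,
    sensor_slope = slope[1], sensor_intercept = intercept[1],
    sensor_type = type[1], sensor_unit = unit[1],
    tag_model_name = "V16", tag_serial_number = "000001",
    tag_expected_life_time_days = 1000, tag_status = "deployed",
    sex = NA_character_, measurement = NA_character_,
    stringsAsFactors = FALSE
  )
  d$transmitter_ids <- I(list(sort(tid)))
  d$dual_sensor_tag <- length(tid) > 1
  d$transmitter_sensors <- I(list(data.frame(
    transmitter_id = tid,
    sensor_slope = rep_len(slope, length(tid)),
    sensor_intercept = rep_len(intercept, length(tid)),
    sensor_type = rep_len(type, length(tid)),
    sensor_unit = rep_len(unit, length(tid)),
    stringsAsFactors = FALSE
  )))
  d
}

fake_stations <- function(lon, lat, station = paste0("S", seq_along(lon)),
                          installation = "I1", habitat = "ocean") {
  data.frame(
    installation_name = rep_len(installation, length(lon)),
    station_name = station,
    longitude = lon, latitude = lat,
    habitat = rep_len(habitat, length(lon)),
    stringsAsFactors = FALSE
  )
}

fake_metrics <- function(dist_prev = NA, dist_next = NA,
                         vel_prev = NA, vel_next = NA) {
  data.frame(dist_prev = dist_prev, dist_next = dist_next,
             vel_prev = vel_prev, vel_next = vel_next)
}

# Attach hidden truth labels to flagged detections ("clean" where no label).
label_detections <- function(qc, truth) {
  key <- paste(qc$transmitter_id,
               format(qc$detection_timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
               qc$station_name)
  truth_key <- paste(truth$transmitter_id, truth$detection_timestamp,
                     truth$station_name)
  lab <- truth$label[match(key, truth_key)]
  lab[is.na(lab)] <- "clean"
  lab
}

# QC every deployment of a simulated scenario; returns flagged detections
# with a `label` column.
qc_simulated <- function(sim, config = qc_config()) {
  tf <- tempfile(fileext = ".csv")
  tagqc:::write_qc_csv(sim$tag_metadata, tf)
  deps <- read_tag_metadata(tf)
  cache <- new_trip_cache()
  out <- lapply(seq_len(nrow(deps)), function(i) {
    dd <- sim$detections[
      sim$detections$transmitter_id %in% deps$transmitter_ids[[i]], ,
      drop = FALSE
    ]
    qc_deployment(deps[i, , drop = FALSE], dd, sim$stations,
                  sim$seascape$surface, sim$distributions, config, cache)$qc
  })
  qc <- do.call(rbind, out)
  qc$label <- label_detections(qc, sim$truth)
  qc
}
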