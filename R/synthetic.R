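# Synthetic scenario generator.
#
# Emulates, at desk scale, the data model of a continental acoustic network:
# a seascape (land/water geometry), a station network grouped into
# installations, tag deployments, animal tracks (correlated random walks with
# home attraction, reflected off land), detection emission within receiver
# range, and injected contamination with hidden truth labels. Everything is
# driven by one seed, so scenarios are exactly reproducible.
#
# Geometry of the default (open_water) scenario: a 45 x 35 degree all-water
# box; clean installations are curtains of stations 800 m apart clustered in
# the south-west; injected "teleport" stations sit in the north-east corner
# (> 3,000 km from the cluster, comfortably beyond the 1,000 km distance
# threshold) and injected out-of-distribution stations in the south-east
# (> 500 km outside any species distribution built around the cluster).
# Station spacing (800 m), detection range (300 m) and step length (60 m per
# 60 s, a ~1 m/s swim) are chosen so that consecutive detections of a clean
# track can never imply a swim speed above the 10 m/s threshold: two stations
# can both be within range one step apart only if their spacing is below
# 2 * range + 2 * step = 720 m, which the 800 m spacing excludes.

SIM_ORIGIN <- as.POSIXct("2012-01-01 00:00:00", tz = "UTC")

#' Define a synthetic QC scenario
#'
#' @param seed Integer seed fixing every random draw.
#' @param seascape One of `"open_water"`, `"square_island"`, `"bay"`,
#'   `"river_and_coast"`.
#' @param n_installations,stations_per_installation Network size (defaults
#'   5 x 5).
#' @param n_deployments Number of tag deployments (default 6); deployment d
#'   is released at installation `((d - 1) %% n_installations) + 1`.
#' @param n_steps Track length in steps (default 3000; one step = `step_s`).
#' @param step_s Step duration, seconds (default 60).
#' @param step_m Step length, metres (default 60; ~1 m/s swim speed).
#' @param turning_rho Turning-angle concentration of the correlated random
#'   walk in [0, 1) (default 0.8).
#' @param confine_m Home-attraction radius around the release installation,
#'   metres (default 2,000): beyond it the heading is re-aimed home.
#' @param detect_p Detection probability per step while within range
#'   (default 0.8).
#' @param detection_range_m Receiver detection range, metres (default 300,
#'   within the 60--950 m envelope of field receivers).
#' @param contamination Named list of injected-record counts across the whole
#'   scenario: `false_single_hit`, `pre_release`, `teleport`,
#'   `out_of_distribution` (default 10 each). Teleport and
#'   out-of-distribution injections require the `open_water` seascape, whose
#'   extent exceeds the thresholds they must violate.
#' @param species Character vector of species names cycled over deployments.
#' @return A `sim_scenario` object.
#' @export
sim_scenario <- function(seed,
                         seascape = "open_water",
                         n_installations = 5,
                         stations_per_installation = 5,
                         n_deployments = 6,
                         n_steps = 3000,
                         step_s = 60,
                         step_m = 60,
                         turning_rho = 0.8,
                         confine_m = 2000,
                         detect_p = 0.8,
                         detection_range_m = 300,
                         contamination = list(false_single_hit = 10,
                                              pre_release = 10,
                                              teleport = 10,
                                              out_of_distribution = 10),
                         species = c("Galeocerdo cuvier",
                                     "Carcharhinus amblyrhynchos")) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop("a seed is required: synthetic scenarios must be reproducible")
  }
  seascape <- match.arg(seascape,
    c("open_water", "square_island", "bay", "river_and_coast"))
  defaults <- list(false_single_hit = 0, pre_release = 0, teleport = 0,
                   out_of_distribution = 0)
  unknown <- setdiff(names(contamination), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown contamination class(es): ", paste(unknown, collapse = ", "))
  }
  defaults[names(contamination)] <- contamination
  contamination <- lapply(defaults, as.integer)
  if (any(unlist(contamination) < 0)) stop("contamination counts must be >= 0")
  if ((contamination$teleport > 0 || contamination$out_of_distribution > 0) &&
      seascape != "open_water") {
    stop("teleport/out_of_distribution injections need the open_water seascape")
  }
  structure(list(
    seed = as.integer(seed), seascape = seascape,
    n_installations = n_installations,
    stations_per_installation = stations_per_installation,
    n_deployments = n_deployments,
    n_steps = n_steps, step_s = step_s, step_m = step_m,
    turning_rho = turning_rho, confine_m = confine_m,
    detect_p = detect_p, detection_range_m = detection_range_m,
    contamination = contamination, species = species
  ), class = "sim_scenario")
}

#' Build an analytic synthetic seascape
#'
#' Returns land polygons whose rasterisation is exactly predictable at the
#' chosen resolution, plus the rasterised cost surface:
#' * `open_water`: a 45 x 35 degree all-water box, no land cells;
#' * `square_island`: a 1 x 1 degree island centred in a 10 x 10 degree box;
#' * `bay`: an eastern land mass indented by a rectangular bay with one
#'   west-facing mouth;
#' * `river_and_coast`: an eastern land mass pierced by a one-cell-wide
#'   west-flowing river channel.
#'
#' @param spec Seascape name (see above).
#' @param resolution Raster resolution in degrees (default 0.25 for
#'   `open_water`, 0.1 otherwise).
#' @return A list with `spec`, `polygons`, `bounds`, `resolution`, and the
#'   rasterised `surface`.
#' @export
make_seascape <- function(spec, resolution = NULL) {
  spec <- match.arg(spec,
    c("open_water", "square_island", "bay", "river_and_coast"))
  if (spec == "open_water") {
    bounds <- c(xmin = 110, xmax = 155, ymin = -45, ymax = -10)
    if (is.null(resolution)) resolution <- 0.25
    polygons <- list()
  } else {
    bounds <- c(xmin = 140, xmax = 150, ymin = -40, ymax = -30)
    if (is.null(resolution)) resolution <- 0.1
    polygons <- switch(spec,
      square_island = list(rect_ring(144.5, -35.5, 145.5, -34.5)),
      bay = list(close_ring(cbind(
        lon = c(147, 150, 150, 147, 147, 148.5, 148.5, 147),
        lat = c(-38, -38, -32, -32, -34.5, -34.5, -35.5, -35.5)
      ))),
      river_and_coast = list(close_ring(cbind(
        lon = c(147, 150, 150, 147, 147, 149, 149, 147),
        lat = c(-40, -40, -30, -30, -34.9, -34.9, -35.0, -35.0)
      )))
    )
  }
  surface <- build_cost_surface(polygons, resolution, bounds)
  list(spec = spec, polygons = polygons, bounds = bounds,
       resolution = resolution, surface = surface)
}

# Degrees of latitude per metre on the 6,371 km sphere.
DEG_PER_M <- 180 / (pi * EARTH_RADIUS_M)

# Deterministic station network: installations are north-south "curtains" of
# stations 800 m apart; river_and_coast replaces the last installation with
# stations along the river channel (habitat "river").
place_stations <- function(seascape, n_installations,
                           stations_per_installation, spacing_m = 800) {
  cluster <- switch(seascape$spec,
    open_water = c(115, -32),
    c(141, -35) # open water west of the land features in the 10-degree boxes
  )
  rows <- list()
  for (i in seq_len(n_installations)) {
    inst <- sprintf("INST%02d", i)
    river <- seascape$spec == "river_and_coast" && i == n_installations
    for (j in seq_len(stations_per_installation)) {
      if (river) {
        lon <- 147.2 + (j - 1) * 0.4
        lat <- -34.95
        habitat <- "river"
      } else {
        lon <- cluster[1] + (i - 1) * 0.3
        lat <- cluster[2] +
          (j - (stations_per_installation + 1) / 2) * spacing_m * DEG_PER_M
        habitat <- "ocean"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        installation_name = inst,
        station_name = sprintf("%s-S%d", inst, j),
        longitude = lon, latitude = lat, habitat = habitat,
        receiver_name = sprintf("VR2W-%d", 100000 + (i - 1) * 100 + j),
        stringsAsFactors = FALSE
      )
    }
  }
  st <- do.call(rbind, rows)
  cell <- cell_from_xy(seascape$surface, st$longitude, st$latitude)
  if (anyNA(cell) || any(is_land_cell(seascape$surface, cell) &
                         st$habitat != "river")) {
    stop("station placement produced an ocean station on land")
  }
  st
}

# Correlated random walk with home attraction, reflected off land. Returns
# the emitted detections (one row per detection, unique timestamps).
simulate_track_detections <- function(scn, seascape, stations_inst,
                                      release, release_time, transmitter_ids,
                                      sensor_raw = FALSE) {
  surface <- seascape$surface
  centre <- c(
    mean(stations_inst$longitude),
    mean(stations_inst$latitude)
  )
  pos <- c(release$lon, release$lat)
  heading <- runif(1, 0, 360)
  sd_turn <- (1 - scn$turning_rho) * 180
  out <- vector("list", scn$n_steps)
  n_out <- 0L
  for (t in seq_len(scn$n_steps)) {
    if (great_circle_distance(pos[1], pos[2], centre[1], centre[2]) >
        scn$confine_m) {
      heading <- geosphere::bearing(pos, centre) + rnorm(1, 0, 15)
    } else {
      heading <- heading + rnorm(1, 0, sd_turn)
    }
    moved <- FALSE
    for (try in seq_len(100)) {
      cand <- geosphere::destPoint(pos, heading, scn$step_m,
                                   r = EARTH_RADIUS_M)
      cell <- cell_from_xy(surface, cand[1], cand[2])
      if (!is.na(cell) && !is_land_cell(surface, cell)) {
        moved <- TRUE
        break
      }
      heading <- runif(1, 0, 360)
    }
    if (moved) pos <- c(cand[1], cand[2])
    d <- great_circle_distance(pos[1], pos[2],
                               stations_inst$longitude,
                               stations_inst$latitude)
    in_range <- which(d <= scn$detection_range_m)
    if (length(in_range) > 0 && runif(1) < scn$detect_p) {
      j <- in_range[which.min(d[in_range])]
      n_out <- n_out + 1L
      out[[n_out]] <- data.frame(
        transmitter_id = if (length(transmitter_ids) > 1) {
          sample(transmitter_ids, 1)
        } else transmitter_ids,
        installation_name = stations_inst$installation_name[j],
        station_name = stations_inst$station_name[j],
        receiver_name = stations_inst$receiver_name[j],
        detection_timestamp = release_time + t * scn$step_s,
        longitude = stations_inst$longitude[j],
        latitude = stations_inst$latitude[j],
        sensor_value = if (sensor_raw) sample(0:255, 1) else NA_real_,
        sensor_unit = if (sensor_raw) "ADC" else NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (n_out == 0) return(NULL)
  do.call(rbind, out[seq_len(n_out)])
}

#' Build a species expert-distribution polygon set
#'
#' @param species Scientific name.
#' @param core_ring A closed lon/lat ring for the core occurrence area.
#' @param dir Optional directory; when given, the distribution is written to
#'   `<dir>/<species with underscores>.geojson`.
#' @return The polygon list, with attribute `"path"` when written.
#' @export
make_distribution <- function(species, core_ring, dir = NULL) {
  polygons <- list(close_ring(core_ring))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- file.path(dir, paste0(gsub(" ", "_", species), ".geojson"))
    write_geojson_polygons(polygons, path)
    attr(polygons, "path") <- path
  }
  polygons
}

# Pick gap indices (a gap g sits between clean detections g and g+1) for the
# injections of one deployment. "Far" injections (teleport /
# out-of-distribution) are kept >= 2 gaps apart so that no clean detection
# ever has far injections on both sides; single-hit injections prefer long
# gaps so their implied swim speeds stay low. All chosen gaps are distinct.
choose_injection_gaps <- function(ts, n_far, n_single) {
  n <- length(ts)
  interior <- seq(2L, n - 2L)
  if (n < 5 || length(interior) < 3 * n_far + n_single) {
    stop("track produced too few detections for the requested contamination")
  }
  far_pool <- interior[seq(1L, length(interior), by = 3L)]
  if (length(far_pool) < n_far) {
    stop("track produced too few detections for the requested contamination")
  }
  far <- far_pool[seq_len(n_far)]
  dt <- diff(as.numeric(ts))
  used <- far
  pick_single <- function(min_dt) {
    cand <- setdiff(interior[dt[interior] >= min_dt], used)
    cand[seq_len(min(length(cand), n_single - length(single)))]
  }
  single <- integer(0)
  for (min_dt in c(1200, 600, 2)) {
    if (length(single) >= n_single) break
    add <- pick_single(min_dt)
    single <- c(single, add)
    used <- c(used, add)
  }
  if (length(single) < n_single) {
    stop("track produced too few detections for the requested contamination")
  }
  list(far = far, single = sort(single))
}

mid_time <- function(t1, t2) {
  as.POSIXct(floor((as.numeric(t1) + as.numeric(t2)) / 2),
    origin = "1970-01-01", tz = "UTC")
}

#' Simulate a full synthetic scenario
#'
#' Builds the seascape, station network, tag deployments (one is a
#' dual-sensor temperature/pressure tag), animal tracks and detections, and
#' injects the requested contamination with truth labels. Optionally writes
#' the six interchange files (detections, tag metadata, station registry,
#' land polygons, per-species distributions, truth labels).
#'
#' @param scenario A [sim_scenario()].
#' @param out_dir Optional output directory.
#' @return A list with `seascape`, `stations`, `tag_metadata` (deployment
#'   rows as written), `deployments` (parsed, one row per deployment),
#'   `detections`, `truth`, `distributions` (named list of polygon sets) and,
#'   when written, `paths`.
#' @export
simulate_scenario <- function(scenario, out_dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  scn <- scenario
  set.seed(scn$seed)
  seascape <- make_seascape(scn$seascape)
  stations <- place_stations(seascape, scn$n_installations,
                             scn$stations_per_installation)

  # distribution: station cluster bounding box padded by one degree
  core <- rect_ring(
    min(stations$longitude) - 1, min(stations$latitude) - 1,
    max(stations$longitude) + 1, max(stations$latitude) + 1
  )
  species_list <- unique(scn$species)
  distributions <- stats::setNames(
    lapply(species_list, function(sp) make_distribution(sp, core)),
    species_list
  )

  # contamination assignment: injection j of a class goes to deployment
  # ((j - 1) %% n_deployments) + 1
  per_dep <- function(total) {
    vapply(seq_len(scn$n_deployments), function(d) {
      sum(((seq_len(total) - 1L) %% scn$n_deployments) + 1L == d)
    }, integer(1))
  }
  n_tele <- per_dep(scn$contamination$teleport)
  n_ood <- per_dep(scn$contamination$out_of_distribution)
  n_single <- per_dep(scn$contamination$false_single_hit)
  n_pre <- per_dep(scn$contamination$pre_release)

  b <- seascape$bounds
  far_tele <- function(k) {
    unname(c(b["xmax"] - 1 - 0.05 * k, b["ymax"] - 1 - 0.05 * k))
  }
  far_ood <- function(k) {
    unname(c(b["xmax"] - 3 - 0.05 * k, b["ymin"] + 1 + 0.05 * k))
  }

  meta_rows <- list(); det_all <- list(); truth <- list()
  extra_stations <- list()
  k_tele <- 0L; k_ood <- 0L; k_single <- 0L

  add_station <- function(inst, name, lon, lat, receiver) {
    extra_stations[[length(extra_stations) + 1L]] <<- data.frame(
      installation_name = inst, station_name = name,
      longitude = lon, latitude = lat, habitat = "ocean",
      receiver_name = receiver, stringsAsFactors = FALSE
    )
  }

  for (d in seq_len(scn$n_deployments)) {
    inst_i <- ((d - 1L) %% scn$n_installations) + 1L
    inst <- sprintf("INST%02d", inst_i)
    st_inst <- stations[stations$installation_name == inst, , drop = FALSE]
    release <- list(lon = st_inst$longitude[1], lat = st_inst$latitude[1])
    release_time <- SIM_ORIGIN
    dual <- d == 1L
    tids <- if (dual) {
      sprintf("A69-9002-%d", c(10000 + d, 20000 + d))
    } else {
      sprintf("A69-9002-%d", 10000 + d)
    }
    sp <- scn$species[((d - 1L) %% length(scn$species)) + 1L]

    # metadata rows (one per transmitter)
    for (ti in seq_along(tids)) {
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        transmitter_id = tids[ti],
        tag_id = sprintf("T%03d", d),
        release_id = "R1",
        tag_project_name = "SYNTH",
        scientific_name = sp,
        common_name = sp,
        release_longitude = release$lon,
        release_latitude = release$lat,
        ReleaseDate = format_timestamp(release_time),
        sensor_slope = if (dual) c(0.1575, 0.3)[ti] else NA_real_,
        sensor_intercept = if (dual) c(-5, 0)[ti] else NA_real_,
        sensor_type = if (dual) c("temperature", "pressure")[ti] else "pinger",
        sensor_unit = if (dual) c("°C", "m")[ti] else NA_character_,
        tag_model_name = if (dual) "V16TP" else "V16",
        tag_serial_number = sprintf("%06d", 500000 + d),
        tag_expected_life_time_days = 1000,
        tag_status = "deployed",
        sex = NA_character_,
        measurement = NA_character_,
        dual_sensor_tag = dual,
        stringsAsFactors = FALSE
      )
    }

    clean <- simulate_track_detections(scn, seascape, st_inst, release,
                                       release_time, tids,
                                       sensor_raw = dual)
    if (is.null(clean)) stop("deployment ", d, " produced no detections")
    clean <- clean[order(clean$detection_timestamp), , drop = FALSE]

    dep_det <- clean
    dep_truth <- list()
    n_far_d <- n_tele[d] + n_ood[d]
    if (n_far_d + n_single[d] > 0) {
      gaps <- choose_injection_gaps(clean$detection_timestamp,
                                    n_far_d, n_single[d])
      far_kinds <- c(rep("teleport", n_tele[d]),
                     rep("out_of_distribution", n_ood[d]))
      for (gi in seq_along(gaps$far)) {
        g <- gaps$far[gi]
        kind <- far_kinds[gi]
        if (kind == "teleport") {
          k_tele <- k_tele + 1L
          p <- far_tele(k_tele)
          inst_name <- sprintf("INJ-TELE-%d", k_tele)
        } else {
          k_ood <- k_ood + 1L
          p <- far_ood(k_ood)
          inst_name <- sprintf("INJ-OOD-%d", k_ood)
        }
        sname <- paste0(inst_name, "-S1")
        rname <- paste0("VR2W-9", inst_name)
        add_station(inst_name, sname, p[1], p[2], rname)
        ts <- mid_time(clean$detection_timestamp[g],
                       clean$detection_timestamp[g + 1])
        row <- data.frame(
          transmitter_id = tids[1], installation_name = inst_name,
          station_name = sname, receiver_name = rname,
          detection_timestamp = ts, longitude = p[1], latitude = p[2],
          sensor_value = NA_real_, sensor_unit = NA_character_,
          stringsAsFactors = FALSE
        )
        dep_det <- rbind(dep_det, row)
        dep_truth[[length(dep_truth) + 1L]] <- data.frame(
          transmitter_id = tids[1], tag_id = sprintf("T%03d", d),
          release_id = "R1", station_name = sname,
          detection_timestamp = format_timestamp(ts), label = kind,
          stringsAsFactors = FALSE
        )
      }
      for (g in gaps$single) {
        k_single <- k_single + 1L
        inst_name <- sprintf("INJ-FDA-%d", k_single)
        sname <- paste0(inst_name, "-S1")
        rname <- paste0("VR2W-9", inst_name)
        centre <- c(mean(st_inst$longitude), mean(st_inst$latitude))
        p <- c(centre[1] + 0.01 + 0.002 * k_single, centre[2] + 0.01)
        add_station(inst_name, sname, p[1], p[2], rname)
        ts <- mid_time(clean$detection_timestamp[g],
                       clean$detection_timestamp[g + 1])
        row <- data.frame(
          transmitter_id = tids[1], installation_name = inst_name,
          station_name = sname, receiver_name = rname,
          detection_timestamp = ts, longitude = p[1], latitude = p[2],
          sensor_value = NA_real_, sensor_unit = NA_character_,
          stringsAsFactors = FALSE
        )
        dep_det <- rbind(dep_det, row)
        dep_truth[[length(dep_truth) + 1L]] <- data.frame(
          transmitter_id = tids[1], tag_id = sprintf("T%03d", d),
          release_id = "R1", station_name = sname,
          detection_timestamp = format_timestamp(ts),
          label = "false_single_hit", stringsAsFactors = FALSE
        )
      }
    }
    if (n_pre[d] > 0) {
      inst_name <- sprintf("INJ-PRE-%d", d)
      sname <- paste0(inst_name, "-S1")
      rname <- paste0("VR2W-9", inst_name)
      p <- c(release$lon + 0.001, release$lat + 0.001)
      add_station(inst_name, sname, p[1], p[2], rname)
      for (k in seq_len(n_pre[d])) {
        ts <- release_time - 10 * 86400 + (k - 1) * 600
        row <- data.frame(
          transmitter_id = tids[1], installation_name = inst_name,
          station_name = sname, receiver_name = rname,
          detection_timestamp = ts, longitude = p[1], latitude = p[2],
          sensor_value = NA_real_, sensor_unit = NA_character_,
          stringsAsFactors = FALSE
        )
        dep_det <- rbind(dep_det, row)
        dep_truth[[length(dep_truth) + 1L]] <- data.frame(
          transmitter_id = tids[1], tag_id = sprintf("T%03d", d),
          release_id = "R1", station_name = sname,
          detection_timestamp = format_timestamp(ts), label = "pre_release",
          stringsAsFactors = FALSE
        )
      }
    }
    det_all[[d]] <- dep_det
    if (length(dep_truth) > 0) {
      truth[[length(truth) + 1L]] <- do.call(rbind, dep_truth)
    }
  }

  detections <- sort_detections(do.call(rbind, det_all))
  truth <- if (length(truth) > 0) do.call(rbind, truth) else data.frame(
    transmitter_id = character(0), tag_id = character(0),
    release_id = character(0), station_name = character(0),
    detection_timestamp = character(0), label = character(0),
    stringsAsFactors = FALSE
  )
  tag_metadata <- do.call(rbind, meta_rows)
  all_stations <- rbind(stations,
                        if (length(extra_stations) > 0) {
                          do.call(rbind, extra_stations)
                        })
  rownames(detections) <- rownames(all_stations) <- NULL

  result <- list(
    scenario = scn, seascape = seascape,
    stations = all_stations, tag_metadata = tag_metadata,
    detections = detections, truth = truth,
    distributions = distributions
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    det_out <- detections
    det_out$detection_timestamp <- format_timestamp(det_out$detection_timestamp)
    paths <- list(
      detections = file.path(out_dir, "detections.csv"),
      tag_metadata = file.path(out_dir, "tag_metadata.csv"),
      stations = file.path(out_dir, "stations.csv"),
      land = file.path(out_dir, "land.geojson"),
      truth = file.path(out_dir, "truth_labels.csv"),
      distributions = file.path(out_dir, "distributions")
    )
    write_qc_csv(det_out, paths$detections)
    write_qc_csv(tag_metadata, paths$tag_metadata)
    st_out <- all_stations[, c("installation_name", "station_name",
                               "longitude", "latitude", "habitat")]
    write_qc_csv(st_out, paths$stations)
    write_geojson_polygons(seascape$polygons, paths$land)
    write_qc_csv(truth, paths$truth)
    for (sp in names(distributions)) {
      make_distribution(sp, distributions[[sp]][[1]], paths$distributions)
    }
    result$paths <- paths
  }
  result
}
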