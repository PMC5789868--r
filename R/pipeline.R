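# End-to-end orchestration: build the cost surface once, iterate deployments,
# write one QC file per deployment plus per-deployment logs, a run summary
# and a machine-readable manifest.

PKG_VERSION <- function() as.character(utils::packageVersion("tagqc"))

# FNV-1a hash of a string, as hex; used to fingerprint the configuration in
# the manifest.
fnv1a_hex <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by 16777619; split to stay within double
    # precision (h < 2^32, so h * 16777619 would lose low bits)
    hi <- floor(h / 65536); lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hex(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA))
}

as_input <- function(x, reader) if (is.character(x)) reader(x) else x

# Load every "<Species_name>.geojson" in a directory into a named polygon
# list (underscores in file names map to spaces in species names).
read_distributions <- function(dir) {
  if (is.null(dir)) return(list())
  files <- list.files(dir, pattern = "\\.geojson$", full.names = TRUE)
  out <- lapply(files, read_geojson_polygons)
  names(out) <- gsub("_", " ",
                     sub("\\.geojson$", "", basename(files)))
  out
}

# Assign each detection of a transmitter to a deployment: the latest release
# dated at or before the detection, or the earliest release for detections
# that precede every release (so pre-release screening can flag them).
assign_deployments <- function(detections, deployments) {
  dep_of <- vector("list", nrow(deployments))
  tid_map <- list()
  for (i in seq_len(nrow(deployments))) {
    for (tid in deployments$transmitter_ids[[i]]) {
      tid_map[[tid]] <- c(tid_map[[tid]], i)
    }
  }
  assign_idx <- rep(NA_integer_, nrow(detections))
  for (tid in names(tid_map)) {
    rows <- which(detections$transmitter_id == tid)
    if (length(rows) == 0) next
    deps <- tid_map[[tid]]
    rel <- as.numeric(deployments$release_datetime[deps])
    o <- order(rel)
    deps <- deps[o]; rel <- rel[o]
    ts <- as.numeric(detections$detection_timestamp[rows])
    pick <- findInterval(ts, rel)
    pick[pick == 0L] <- 1L
    assign_idx[rows] <- deps[pick]
  }
  assign_idx
}

#' Run the QC pipeline end to end
#'
#' Reads detections, tag metadata, the station registry, optional species
#' distributions and land geometry; builds the land/water cost surface once;
#' runs the full QC battery per tag deployment; and writes the output tree:
#' one QC CSV per deployment transmitter (named
#' `TransmitterID_TagID_ReleaseID.csv`), the master tag metadata file,
#' per-deployment logs (`qc_logs.csv`), a run summary (`run_summary.csv`) and
#' a manifest (`manifest.json`). A failing deployment is logged with status
#' `failed` and does not abort the others.
#'
#' @param detections Detections CSV path or data frame ([read_detections()]).
#' @param tags Tag metadata CSV path or data frame ([read_tag_metadata()]).
#' @param stations Station registry CSV path or data frame
#'   ([read_stations()]).
#' @param distributions_dir Directory of per-species `.geojson` distribution
#'   files, or `NULL` (distribution tests then report "not performed").
#' @param land Land polygons: GeoJSON path, ring list, or `NULL` for an
#'   all-water surface.
#' @param out_dir Output directory (created if needed).
#' @param config A [qc_config()].
#' @param resolution Cost-surface resolution in degrees (default 0.05).
#' @param bounds Optional named bounds `c(xmin, xmax, ymin, ymax)`; by
#'   default the extent of stations, detections and release points padded by
#'   one degree.
#' @param directions Water-graph connectivity (default 16).
#' @param input_tz Time zone of input timestamps (default UTC).
#' @return The run manifest (a list), invisibly; `manifest$ok` is `TRUE` when
#'   no deployment failed.
#' @export
qc_run <- function(detections, tags, stations, distributions_dir = NULL,
                   land = NULL, out_dir, config = qc_config(),
                   resolution = 0.05, bounds = NULL, directions = 16,
                   input_tz = "UTC") {
  started <- Sys.time()
  det <- as_input(detections, function(p) read_detections(p, input_tz))
  deployments <- as_input(tags, function(p) read_tag_metadata(p, input_tz))
  st <- as_input(stations, read_stations)
  distributions <- read_distributions(distributions_dir)
  land_polygons <- if (is.null(land)) {
    list()
  } else if (is.character(land)) {
    read_geojson_polygons(land)
  } else {
    land
  }

  if (is.null(bounds)) {
    lons <- c(st$longitude, det$longitude, deployments$release_longitude)
    lats <- c(st$latitude, det$latitude, deployments$release_latitude)
    bounds <- c(
      xmin = min(lons, na.rm = TRUE) - 1, xmax = max(lons, na.rm = TRUE) + 1,
      ymin = min(lats, na.rm = TRUE) - 1, ymax = max(lats, na.rm = TRUE) + 1
    )
  }
  surface <- build_cost_surface(land_polygons, resolution, bounds, directions)
  cache <- new_trip_cache()

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dep_idx <- assign_deployments(det, deployments)

  log_rows <- list(); manifest_rows <- list(); files <- character(0)
  for (i in seq_len(nrow(deployments))) {
    dep <- deployments[i, , drop = FALSE]
    dep_det <- det[which(dep_idx == i), , drop = FALSE]
    res <- tryCatch({
      out <- qc_deployment(dep, dep_det, st, surface, distributions,
                           config, cache)
      paths <- write_qc_file(out$qc, dep, out_dir)
      files <- c(files, paths)
      status <- if (nrow(dep_det) == 0) "empty" else "ok"
      lg <- out$log
      log_rows[[i]] <- data.frame(
        tag_id = lg$tag_id, release_id = lg$release_id,
        transmitter_ids = lg$transmitter_ids,
        scientific_name = lg$scientific_name,
        status = status, n_detections = lg$n_detections,
        fda_fail = lg$fail_counts[["FDA_QC"]],
        velocity_fail = lg$fail_counts[["Velocity_QC"]],
        distance_fail = lg$fail_counts[["Distance_QC"]],
        distribution_fail = lg$fail_counts[["DetectionDistribution_QC"]],
        distance_release_fail = lg$fail_counts[["DistanceRelease_QC"]],
        release_date_fail = lg$fail_counts[["ReleaseDate_QC"]],
        release_location_flag = lg$release_location_flag,
        n_qc1 = lg$composite_counts[1], n_qc2 = lg$composite_counts[2],
        n_qc3 = lg$composite_counts[3], n_qc4 = lg$composite_counts[4],
        frac_valid = lg$frac_valid,
        stringsAsFactors = FALSE
      )
      status
    }, error = function(e) {
      log_rows[[i]] <<- data.frame(
        tag_id = dep$tag_id, release_id = dep$release_id,
        transmitter_ids = paste(dep$transmitter_ids[[1]], collapse = ";"),
        scientific_name = dep$scientific_name,
        status = "failed", n_detections = nrow(dep_det),
        fda_fail = NA_integer_, velocity_fail = NA_integer_,
        distance_fail = NA_integer_, distribution_fail = NA_integer_,
        distance_release_fail = NA_integer_, release_date_fail = NA_integer_,
        release_location_flag = NA_integer_,
        n_qc1 = NA_integer_, n_qc2 = NA_integer_, n_qc3 = NA_integer_,
        n_qc4 = NA_integer_, frac_valid = NA_real_,
        stringsAsFactors = FALSE
      )
      message(sprintf("deployment %s/%s failed: %s",
                      dep$tag_id, dep$release_id, conditionMessage(e)))
      "failed"
    })
    manifest_rows[[i]] <- list(
      tag_id = dep$tag_id, release_id = dep$release_id, status = res,
      n_detections = nrow(dep_det)
    )
  }

  logs <- do.call(rbind, log_rows)
  write_qc_csv(logs, file.path(out_dir, "qc_logs.csv"))

  # master metadata copy (as provided, one row per transmitter)
  meta_src <- if (is.character(tags)) {
    read_csv_chr(tags)
  } else {
    tags
  }
  meta_out <- meta_src
  meta_out$transmitter_ids <- NULL
  meta_out$transmitter_sensors <- NULL
  write_qc_csv(as.data.frame(meta_out), file.path(out_dir, "tag_metadata.csv"))

  ok_rows <- logs[logs$status != "failed" & logs$n_detections > 0, ,
                  drop = FALSE]
  summary <- data.frame(
    n_deployments = nrow(deployments),
    n_failed = sum(logs$status == "failed"),
    n_detections = sum(logs$n_detections, na.rm = TRUE),
    n_qc1 = sum(ok_rows$n_qc1), n_qc2 = sum(ok_rows$n_qc2),
    n_qc3 = sum(ok_rows$n_qc3), n_qc4 = sum(ok_rows$n_qc4)
  )
  write_qc_csv(summary, file.path(out_dir, "run_summary.csv"))

  manifest <- list(
    software = "tagqc", version = PKG_VERSION(),
    started = format_timestamp(started),
    finished = format_timestamp(Sys.time()),
    inputs = list(
      detections = if (is.character(detections)) detections else "<data>",
      tags = if (is.character(tags)) tags else "<data>",
      stations = if (is.character(stations)) stations else "<data>",
      distributions_dir = distributions_dir,
      land = if (is.character(land)) land else if (is.null(land)) NULL
             else "<data>"
    ),
    config = unclass(config),
    config_hash = config_hash(config),
    surface = list(resolution = resolution, directions = directions,
                   bounds = as.list(bounds)),
    deployments = manifest_rows,
    aggregate = as.list(summary),
    ok = all(vapply(manifest_rows, function(r) r$status != "failed",
                    logical(1)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

#' Summarise a completed QC run
#'
#' Aggregates a [qc_run()] output directory into overall and per-species
#' counts and fractions of detections by composite validity (valid,
#' valid-or-likely-valid, invalid-or-likely-invalid), and counts deployments
#' whose every detection was flagged invalid or likely invalid.
#'
#' @param run_dir A directory written by [qc_run()].
#' @return A list with `overall` (one-row data frame), `per_species` (data
#'   frame) and `n_deployments_all_invalid`.
#' @export
summarize_run <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("missing manifest.json: not a completed run directory")
  }
  logs <- read_csv_chr(file.path(run_dir, "qc_logs.csv"))
  num <- function(x) suppressWarnings(as.numeric(x))
  ok <- logs$status %in% c("ok", "empty")
  rows <- logs[ok & num(logs$n_detections) > 0, , drop = FALSE]
  tally <- function(sub) {
    n <- sum(num(sub$n_detections))
    n1 <- sum(num(sub$n_qc1)); n12 <- n1 + sum(num(sub$n_qc2))
    n34 <- sum(num(sub$n_qc3)) + sum(num(sub$n_qc4))
    data.frame(
      n_detections = n, n_valid = n1, n_valid_or_likely = n12,
      n_invalid_or_likely = n34,
      frac_valid = if (n > 0) n1 / n else NA_real_,
      frac_valid_or_likely = if (n > 0) n12 / n else NA_real_,
      frac_invalid_or_likely = if (n > 0) n34 / n else NA_real_
    )
  }
  overall <- tally(rows)
  per_species <- do.call(rbind, lapply(
    split(rows, rows$scientific_name),
    tally
  ))
  per_species <- cbind(
    data.frame(scientific_name = rownames(per_species),
               stringsAsFactors = FALSE),
    per_species
  )
  rownames(per_species) <- NULL
  all_invalid <- sum(
    num(rows$n_qc3) + num(rows$n_qc4) == num(rows$n_detections)
  )
  list(overall = overall, per_species = per_species,
       n_deployments_all_invalid = all_invalid)
}
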