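# Readers and writers for the detection / tag-metadata / station CSV schemas.
#
# Detection files use the QC file schema minus the QC flag columns as their
# input dialect; the writer emits the full schema, one file per tag
# deployment, named "<TransmitterID>_<TagID>_<ReleaseID>.csv". Timestamps are
# "YYYY-MM-DD HH:MM:SS" and are interpreted as UTC unless another input zone
# is given. All CSVs are comma-separated UTF-8 with quoting only where a
# field embeds a comma.

TIMESTAMP_FORMAT <- "%Y-%m-%d %H:%M:%S"

#' @rdname read_detections
#' @export
detection_input_columns <- function() {
  c("transmitter_id", "installation_name", "station_name", "receiver_name",
    "detection_timestamp", "longitude", "latitude")
}

#' @rdname write_qc_file
#' @export
qc_file_columns <- function() {
  c(detection_input_columns(), "sensor_value", "sensor_unit",
    "FDA_QC", "Velocity_QC", "Distance_QC", "DetectionDistribution_QC",
    "DistanceRelease_QC", "ReleaseDate_QC", "ReleaseLocation_QC",
    "Detection_QC")
}

parse_timestamp <- function(x, tz = "UTC") {
  out <- as.POSIXct(x, tz = tz, format = TIMESTAMP_FORMAT)
  if (tz != "UTC") attr(out, "tzone") <- "UTC"
  out
}

format_timestamp <- function(x) format(x, TIMESTAMP_FORMAT, tz = "UTC")

read_csv_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = c("", "NA"), fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
}

# Canonical detection ordering: by transmitter, then time, then station name
# (the station tie-break makes simultaneous detections deterministic).
sort_detections <- function(det) {
  o <- order(det$transmitter_id, det$detection_timestamp, det$station_name,
             method = "radix")
  out <- det[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a detection CSV
#'
#' Reads detection records (the QC file schema minus the flag columns), parses
#' timestamps and coordinates, rejects unparsable rows with a warning naming
#' their line numbers, and returns the detections in canonical order:
#' ascending (transmitter_id, detection_timestamp, station_name).
#'
#' @param path Path to a detection CSV with a header row.
#' @param tz Time zone the input timestamps are recorded in (default UTC;
#'   values are always stored and written as UTC).
#' @return A data frame of detections in canonical order.
#' @export
read_detections <- function(path, tz = "UTC") {
  raw <- read_csv_chr(path)
  require_columns(raw, detection_input_columns(), "detection file")
  n <- nrow(raw)
  ts <- parse_timestamp(raw$detection_timestamp, tz)
  lon <- suppressWarnings(as.numeric(raw$longitude))
  lat <- suppressWarnings(as.numeric(raw$latitude))
  bad <- is.na(ts) | is.na(lon) | is.na(lat) |
    lon < -180 | lon > 180 | lat < -90 | lat > 90
  if (any(bad)) {
    warning(sprintf(
      "rejected %d row(s) with unparsable timestamp/coordinates (line %s)",
      sum(bad), paste(which(bad) + 1L, collapse = ", ")
    ))
  }
  det <- data.frame(
    transmitter_id = raw$transmitter_id,
    installation_name = raw$installation_name,
    station_name = raw$station_name,
    receiver_name = raw$receiver_name,
    detection_timestamp = ts,
    longitude = lon,
    latitude = lat,
    sensor_value = if ("sensor_value" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$sensor_value))
    } else rep(NA_real_, n),
    sensor_unit = if ("sensor_unit" %in% names(raw)) {
      raw$sensor_unit
    } else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  det <- det[!bad, , drop = FALSE]
  sort_detections(det)
}

#' Read the station/installation registry
#'
#' @param path CSV with columns installation_name, station_name, longitude,
#'   latitude and optionally habitat (`ocean` or `river`; defaults to ocean).
#' @return A data frame of stations, one row per (installation, station).
#' @export
read_stations <- function(path) {
  raw <- read_csv_chr(path)
  require_columns(raw, c("installation_name", "station_name",
                         "longitude", "latitude"), "station registry")
  st <- data.frame(
    installation_name = raw$installation_name,
    station_name = raw$station_name,
    longitude = as.numeric(raw$longitude),
    latitude = as.numeric(raw$latitude),
    habitat = if ("habitat" %in% names(raw)) raw$habitat else NA_character_,
    stringsAsFactors = FALSE
  )
  st$habitat[is.na(st$habitat) | !nzchar(st$habitat)] <- "ocean"
  key <- paste(st$installation_name, st$station_name, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (installation_name, station_name) in station registry")
  }
  st
}

#' Read the master tag-metadata file
#'
#' Parses the tag metadata schema and groups rows into deployments: rows
#' sharing a (tag_id, release_id) describe one deployment, and a dual-sensor
#' tag contributes one transmitter ID per row. A tag re-deployed under
#' several release IDs yields several deployments.
#'
#' @param path Path to the metadata CSV.
#' @param tz Time zone of the ReleaseDate column (default UTC).
#' @return A data frame with one row per deployment; `transmitter_ids` is a
#'   list column of transmitter ID vectors and `release_datetime` a UTC
#'   POSIXct parsed from ReleaseDate.
#' @export
read_tag_metadata <- function(path, tz = "UTC") {
  raw <- read_csv_chr(path)
  require_columns(raw, c("transmitter_id", "tag_id", "release_id"),
                  "tag metadata file")
  opt_chr <- function(col) {
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  dup <- duplicated(paste(raw$transmitter_id, raw$release_id, sep = "\r"))
  if (any(dup)) {
    stop("duplicate (transmitter_id, release_id) rows in tag metadata")
  }
  grp <- paste(raw$tag_id, raw$release_id, sep = "\r")
  idx <- split(seq_len(nrow(raw)), grp)
  # sensor calibration is per transmitter (a dual-sensor tag carries e.g. a
  # temperature and a pressure channel with different slopes)
  sensor_cols <- c("sensor_slope", "sensor_intercept", "sensor_type",
                   "sensor_unit")
  shared_cols <- setdiff(names(raw), c("transmitter_id", sensor_cols))
  rows <- lapply(idx, function(i) {
    for (col in shared_cols) {
      vals <- unique(raw[[col]][i])
      if (length(vals[!is.na(vals)]) > 1) {
        stop(sprintf(
          "conflicting values of '%s' for tag %s release %s",
          col, raw$tag_id[i[1]], raw$release_id[i[1]]
        ))
      }
    }
    first <- i[1]
    data.frame(
      tag_id = raw$tag_id[first],
      release_id = raw$release_id[first],
      tag_project_name = opt_chr("tag_project_name")[first],
      scientific_name = opt_chr("scientific_name")[first],
      common_name = opt_chr("common_name")[first],
      release_longitude = as.numeric(opt_chr("release_longitude")[first]),
      release_latitude = as.numeric(opt_chr("release_latitude")[first]),
      release_datetime = parse_timestamp(opt_chr("ReleaseDate")[first], tz),
      sensor_slope = as.numeric(opt_chr("sensor_slope")[first]),
      sensor_intercept = as.numeric(opt_chr("sensor_intercept")[first]),
      sensor_type = opt_chr("sensor_type")[first],
      sensor_unit = opt_chr("sensor_unit")[first],
      tag_model_name = opt_chr("tag_model_name")[first],
      tag_serial_number = opt_chr("tag_serial_number")[first],
      tag_expected_life_time_days =
        as.numeric(opt_chr("tag_expected_life_time_days")[first]),
      tag_status = opt_chr("tag_status")[first],
      sex = opt_chr("sex")[first],
      measurement = opt_chr("measurement")[first],
      stringsAsFactors = FALSE
    )
  })
  dep <- do.call(rbind, rows)
  dep$transmitter_ids <- I(lapply(idx, function(i) sort(raw$transmitter_id[i])))
  dep$dual_sensor_tag <- lengths(dep$transmitter_ids) > 1
  dep$sensor_type[is.na(dep$sensor_type)] <- "pinger"
  # per-transmitter calibration table used by sensor conversion
  dep$transmitter_sensors <- I(lapply(idx, function(i) {
    cal <- data.frame(
      transmitter_id = raw$transmitter_id[i],
      sensor_slope = as.numeric(opt_chr("sensor_slope")[i]),
      sensor_intercept = as.numeric(opt_chr("sensor_intercept")[i]),
      sensor_type = opt_chr("sensor_type")[i],
      sensor_unit = opt_chr("sensor_unit")[i],
      stringsAsFactors = FALSE
    )
    cal$sensor_type[is.na(cal$sensor_type)] <- "pinger"
    cal[order(cal$transmitter_id), , drop = FALSE]
  }))
  needs_cal <- vapply(dep$transmitter_sensors, function(cal) {
    any(cal$sensor_type != "pinger" &
          (is.na(cal$sensor_slope) | is.na(cal$sensor_intercept)))
  }, logical(1))
  if (any(needs_cal)) {
    warning(sprintf(
      "%d sensor-tag deployment(s) lack slope/intercept; raw values kept as ADC",
      sum(needs_cal)
    ))
  }
  rownames(dep) <- NULL
  dep
}

#' Convert a raw sensor reading to physical units
#'
#' Acoustic receivers log sensor payloads as raw integers in 0--255; the
#' physical measurement is the linear transform `slope * raw + intercept`
#' with tag-specific calibration from the metadata.
#'
#' @param raw Raw sensor value(s), 0--255.
#' @param slope,intercept Calibration coefficients (finite reals).
#' @return Numeric physical value(s).
#' @examples
#' convert_sensor(255, 0.2, 1) # 52
#' @export
convert_sensor <- function(raw, slope, intercept) {
  if (any(!is.finite(raw)) || any(raw < 0) || any(raw > 255)) {
    stop("raw sensor values must lie in 0-255")
  }
  stopifnot(all(is.finite(slope)), all(is.finite(intercept)))
  slope * raw + intercept
}

# Apply per-transmitter sensor calibration to a deployment's detections:
# values still in ADC are converted when the transmitter carries slope and
# intercept; otherwise they stay raw with sensor_unit "ADC".
apply_sensor_conversion <- function(det, deployment) {
  if (nrow(det) == 0) return(det)
  unit <- det$sensor_unit
  unit[is.na(unit) & !is.na(det$sensor_value)] <- "ADC"
  det$sensor_unit <- unit
  cal <- deployment$transmitter_sensors[[1]]
  if (is.null(cal)) return(det)
  for (r in seq_len(nrow(cal))) {
    if (is.na(cal$sensor_slope[r]) || is.na(cal$sensor_intercept[r])) next
    adc <- !is.na(det$sensor_value) & det$sensor_unit == "ADC" &
      det$transmitter_id == cal$transmitter_id[r]
    if (!any(adc)) next
    det$sensor_value[adc] <- convert_sensor(
      det$sensor_value[adc], cal$sensor_slope[r], cal$sensor_intercept[r]
    )
    target_unit <- cal$sensor_unit[r]
    if (is.na(target_unit) || !nzchar(target_unit)) {
      target_unit <- switch(cal$sensor_type[r],
        temperature = "°C", pressure = "m", accelerometer = "m/s²", "ADC")
    }
    det$sensor_unit[adc] <- target_unit
  }
  det
}

# Write one CSV in the dialect used throughout: comma-separated UTF-8,
# quoting only fields that embed a comma or a quote.
write_qc_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  quote_field <- function(x) {
    x[is.na(x)] <- ""
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  cells <- vapply(df, function(col) quote_field(as.character(col)),
                  character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  lines <- c(
    paste(quote_field(names(df)), collapse = ","),
    if (nrow(df) > 0) apply(cells, 1, paste, collapse = ",")
  )
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Write per-deployment QC detection files
#'
#' Writes one CSV per transmitter ID of the deployment (dual-sensor tags get
#' one file per transmitter), named `<TransmitterID>_<TagID>_<ReleaseID>.csv`,
#' with exactly the QC schema columns in schema order. A deployment with no
#' detections still produces a header-only file, so the file census matches
#' the metadata census. Coordinates are written with six decimal places.
#'
#' @param qc Data frame of flagged detections (detection fields plus the
#'   seven component flags and Detection_QC).
#' @param deployment One deployment row from [read_tag_metadata()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the file path(s) written.
#' @export
write_qc_file <- function(qc, deployment, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  tids <- deployment$transmitter_ids[[1]]
  if (nrow(qc) > 0 && !all(qc$transmitter_id %in% tids)) {
    stop("detections contain transmitter IDs not in this deployment")
  }
  flag_cols <- setdiff(qc_file_columns(), detection_input_columns())
  paths <- character(0)
  for (tid in tids) {
    rows <- qc[qc$transmitter_id == tid, , drop = FALSE]
    out <- data.frame(
      transmitter_id = rows$transmitter_id,
      installation_name = rows$installation_name,
      station_name = rows$station_name,
      receiver_name = rows$receiver_name,
      detection_timestamp = format_timestamp(rows$detection_timestamp),
      longitude = sprintf("%.6f", rows$longitude),
      latitude = sprintf("%.6f", rows$latitude),
      sensor_value = ifelse(is.na(rows$sensor_value), "",
                            as.character(rows$sensor_value)),
      sensor_unit = rows$sensor_unit,
      stringsAsFactors = FALSE
    )
    for (col in setdiff(flag_cols, c("sensor_value", "sensor_unit"))) {
      out[[col]] <- as.integer(rows[[col]])
    }
    if (nrow(rows) == 0) out <- out[0, , drop = FALSE]
    path <- file.path(out_dir, sprintf(
      "%s_%s_%s.csv", tid, deployment$tag_id, deployment$release_id
    ))
    write_qc_csv(out, path)
    paths <- c(paths, path)
  }
  paths
}
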