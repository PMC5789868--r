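#' QC configuration
#'
#' Thresholds and tolerances for the detection QC tests. Defaults are the
#' operational values of the national quality-control procedure:
#'
#' * false-detection algorithm: detections at an installation are suspect
#'   when intervals longer than 12 h outnumber intervals shorter than 30 min;
#' * movement: a detection fails when both neighbouring trip distances exceed
#'   1,000 km, or both implied swim speeds exceed 10 m/s;
#' * ecology: detections outside the species distribution buffered by 500 km
#'   fail the distribution test; detections more than 500 km from the release
#'   point fail the distance-from-release test;
#' * release date: detections earlier than the release date minus a grace
#'   window (24 h by default, absorbing time-zone discrepancies) fail;
#' * simultaneous detections on two receivers are assigned a 1 s interval so
#'   a swim speed can be computed.
#'
#' @param fda_long_interval_s Long-interval cutoff, seconds (default 12 h).
#' @param fda_short_interval_s Short-interval cutoff, seconds (default 30 min).
#' @param distance_threshold_m Neighbour-distance cutoff, metres (default
#'   1,000 km). Strict: a distance exactly at the threshold passes.
#' @param velocity_threshold_ms Swim-speed cutoff, m/s (default 10). Strict.
#' @param distribution_buffer_m Geodesic buffer around the species
#'   distribution, metres (default 500 km).
#' @param release_radius_m Radius around the release location, metres
#'   (default 500 km). Inclusive: exactly 500 km passes.
#' @param release_date_grace_s Grace window before the release date, seconds
#'   (default 24 h).
#' @param simultaneous_dt_s Interval substituted for simultaneous detections,
#'   seconds (default 1).
#' @return A `qc_config` list.
#' @export
qc_config <- function(fda_long_interval_s = 12 * 3600,
                      fda_short_interval_s = 30 * 60,
                      distance_threshold_m = 1e6,
                      velocity_threshold_ms = 10,
                      distribution_buffer_m = 5e5,
                      release_radius_m = 5e5,
                      release_date_grace_s = 24 * 3600,
                      simultaneous_dt_s = 1) {
  cfg <- list(
    fda_long_interval_s = fda_long_interval_s,
    fda_short_interval_s = fda_short_interval_s,
    distance_threshold_m = distance_threshold_m,
    velocity_threshold_ms = velocity_threshold_ms,
    distribution_buffer_m = distribution_buffer_m,
    release_radius_m = release_radius_m,
    release_date_grace_s = release_date_grace_s,
    simultaneous_dt_s = simultaneous_dt_s
  )
  if (any(vapply(cfg, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop("all qc_config values must be positive numbers")
  }
  if (cfg$fda_short_interval_s >= cfg$fda_long_interval_s) {
    stop("fda_short_interval_s must be smaller than fda_long_interval_s")
  }
  structure(cfg, class = "qc_config")
}

#' Read a flat key = value configuration file overriding QC defaults
#'
#' Lines are `key = value` (seconds / metres / m-per-s as in [qc_config()]);
#' `#` starts a comment. Unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A `qc_config`.
#' @export
read_qc_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    if (!key %in% names(formals(qc_config))) stop("unknown config key: ", key)
    if (is.na(val)) stop("non-numeric config value for ", key)
    args[[key]] <- val
  }
  do.call(qc_config, args)
}
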