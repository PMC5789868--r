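# The seven per-detection QC tests and the composite flag.
#
# Flag conventions: 1 = passed, 2 = failed; 3 = test not performed (only for
# the two tests that depend on an expert species distribution). The composite
# Detection_QC summarises five of the tests (FDA, Distance, Velocity,
# DetectionDistribution, DistanceRelease); ReleaseDate_QC and
# ReleaseLocation_QC are reported alongside but not composited.

#' False-detection algorithm (interval-ratio test)
#'
#' Detections of one tag are grouped by installation. A group fails (flag 2
#' for every detection in it) when the tag was detected only once at that
#' installation, or when intervals between consecutive detections longer than
#' 12 h outnumber intervals shorter than 30 min; intervals in between count
#' for neither side. Such patterns are characteristic of tag-collision false
#' detections rather than a resident animal.
#'
#' @param det Data frame of one deployment's detections in canonical
#'   (chronological) order.
#' @param config A [qc_config()].
#' @return Integer vector of FDA flags (1 or 2), one per detection.
#' @export
fda_test <- function(det, config = qc_config()) {
  flags <- integer(nrow(det))
  if (nrow(det) == 0) return(flags)
  for (inst in unique(det$installation_name)) {
    i <- which(det$installation_name == inst)
    if (length(i) == 1) {
      flags[i] <- 2L
      next
    }
    iv <- diff(as.numeric(det$detection_timestamp[i]))
    n_long <- sum(iv > config$fda_long_interval_s)
    n_short <- sum(iv < config$fda_short_interval_s)
    flags[i] <- if (n_long > n_short) 2L else 1L
  }
  flags
}

#' Distances and swim speeds to neighbouring detections
#'
#' For each detection of one deployment (in chronological order), computes
#' the trip distance and implied swim speed to the previous and next
#' detections. Distances follow the trip rule of [trip_distance()] (straight
#' over water, least-cost around land, composite for river stations).
#' Simultaneous detections on two receivers get a 1 s interval so a speed can
#' be computed. The first detection has no previous metrics and the last no
#' next metrics (`NA`).
#'
#' @param det Detections of one deployment in canonical order.
#' @param stations Station registry data frame ([read_stations()]).
#' @param surface A [build_cost_surface()] object.
#' @param cache Optional [new_trip_cache()].
#' @param config A [qc_config()].
#' @return Data frame with columns dist_prev, dist_next (m), vel_prev,
#'   vel_next (m/s).
#' @export
neighbour_metrics <- function(det, stations, surface, cache = NULL,
                              config = qc_config()) {
  n <- nrow(det)
  out <- data.frame(
    dist_prev = rep(NA_real_, n), dist_next = rep(NA_real_, n),
    vel_prev = rep(NA_real_, n), vel_next = rep(NA_real_, n)
  )
  if (n < 2) return(out)
  skey <- paste(stations$installation_name, stations$station_name, sep = "\r")
  lookup <- function(i) {
    k <- paste(det$installation_name[i], det$station_name[i], sep = "\r")
    j <- match(k, skey)
    if (is.na(j)) {
      stop(sprintf("unknown station '%s' (installation '%s')",
                   det$station_name[i], det$installation_name[i]))
    }
    as.list(stations[j, , drop = FALSE])
  }
  for (i in seq_len(n - 1)) {
    a <- lookup(i); b <- lookup(i + 1)
    d <- trip_distance(a, b, surface, cache)$distance_m
    dt <- as.numeric(det$detection_timestamp[i + 1]) -
      as.numeric(det$detection_timestamp[i])
    dt <- max(dt, config$simultaneous_dt_s)
    v <- d / dt
    out$dist_next[i] <- d; out$vel_next[i] <- v
    out$dist_prev[i + 1] <- d; out$vel_prev[i + 1] <- v
  }
  out
}

# Shared "both neighbours exceed a strict threshold" rule. A detection with a
# single neighbour is judged on that neighbour alone; a detection with no
# neighbours passes vacuously.
both_exceed_flag <- function(prev, nxt, threshold) {
  n <- length(prev)
  flags <- integer(n)
  for (i in seq_len(n)) {
    vals <- c(prev[i], nxt[i])
    vals <- vals[!is.na(vals)]
    flags[i] <- if (length(vals) > 0 && all(vals > threshold)) 2L else 1L
  }
  flags
}

#' Neighbour-distance test
#'
#' A detection fails (flag 2) when every available neighbour trip distance
#' strictly exceeds the threshold (default 1,000 km); an unreachable
#' over-water pair counts as infinite distance and therefore fails.
#'
#' @param metrics Output of [neighbour_metrics()].
#' @param config A [qc_config()].
#' @return Integer vector of Distance_QC flags.
#' @export
distance_test <- function(metrics, config = qc_config()) {
  both_exceed_flag(metrics$dist_prev, metrics$dist_next,
                   config$distance_threshold_m)
}

#' Swim-speed test
#'
#' A detection fails (flag 2) when every available neighbour swim speed
#' strictly exceeds the threshold (default 10 m/s, the fastest recorded
#' sustained speeds among tracked species).
#'
#' @inheritParams distance_test
#' @return Integer vector of Velocity_QC flags.
#' @export
velocity_test <- function(metrics, config = qc_config()) {
  both_exceed_flag(metrics$vel_prev, metrics$vel_next,
                   config$velocity_threshold_ms)
}

#' Species-distribution test
#'
#' A detection passes (flag 1) when it falls within the species expert
#' distribution polygons buffered geodesically by `buffer_m` (default 500 km,
#' absorbing mapping uncertainty and range shifts), fails (flag 2) otherwise.
#' When no distribution is available for the species the test is not
#' performed (flag 3).
#'
#' @param det Detections data frame.
#' @param polygons Species distribution rings (list of lon/lat matrices), or
#'   `NULL` when no distribution exists for the species.
#' @param buffer_m Buffer in metres.
#' @return Integer vector of DetectionDistribution_QC flags (1, 2 or 3).
#' @export
distribution_test <- function(det, polygons, buffer_m = 5e5) {
  if (is.null(polygons) || length(polygons) == 0) {
    return(rep(3L, nrow(det)))
  }
  ok <- within_buffered_polygons(det$longitude, det$latitude, polygons,
                                 buffer_m)
  ifelse(ok, 1L, 2L)
}

#' Distance-from-release test
#'
#' A detection passes (flag 1) when it lies within `radius_m` (default
#' 500 km, inclusive) of the release location by great-circle distance.
#' Missing release coordinates fail the test with a warning.
#'
#' @param det Detections data frame.
#' @param deployment One deployment row.
#' @param radius_m Radius in metres.
#' @return Integer vector of DistanceRelease_QC flags.
#' @export
distance_release_test <- function(det, deployment, radius_m = 5e5) {
  if (is.na(deployment$release_longitude) ||
      is.na(deployment$release_latitude)) {
    warning(sprintf(
      "deployment %s/%s has no release coordinates; DistanceRelease_QC set to 2",
      deployment$tag_id, deployment$release_id
    ))
    return(rep(2L, nrow(det)))
  }
  d <- great_circle_distance(det$longitude, det$latitude,
                             deployment$release_longitude,
                             deployment$release_latitude)
  ifelse(d <= radius_m, 1L, 2L)
}

#' Release-date test
#'
#' A detection fails (flag 2) when it is timestamped earlier than the release
#' date minus a grace window (default 24 h, absorbing time-zone
#' discrepancies in reported release dates).
#'
#' @param det Detections data frame.
#' @param deployment One deployment row with `release_datetime`.
#' @param grace_s Grace window in seconds.
#' @return Integer vector of ReleaseDate_QC flags.
#' @export
release_date_test <- function(det, deployment, grace_s = 24 * 3600) {
  if (is.na(deployment$release_datetime)) return(rep(1L, nrow(det)))
  early <- as.numeric(det$detection_timestamp) <
    (as.numeric(deployment$release_datetime) - grace_s)
  ifelse(early, 2L, 1L)
}

#' Release-location plausibility test (one value per deployment)
#'
#' The release location is plausible (flag 1) when it falls inside the
#' buffered species distribution or within `radius_m` of the tag's first
#' detection. It fails (flag 2) when at least one of those checks can be
#' evaluated and every evaluable check fails, and is not performed (flag 3)
#' when neither check is evaluable (no distribution and no detections).
#'
#' @param deployment One deployment row.
#' @param first_det One-row data frame with the chronologically first
#'   detection, or `NULL` when the deployment has none.
#' @param polygons Species distribution rings or `NULL`.
#' @param radius_m Radius in metres (default 500 km).
#' @param buffer_m Distribution buffer in metres (default 500 km).
#' @return A single integer flag (1, 2 or 3), to be copied to every
#'   detection of the deployment.
#' @export
release_location_test <- function(deployment, first_det, polygons,
                                  radius_m = 5e5, buffer_m = 5e5) {
  checks <- logical(0)
  if (!is.null(polygons) && length(polygons) > 0 &&
      !is.na(deployment$release_longitude) &&
      !is.na(deployment$release_latitude)) {
    checks <- c(checks, within_buffered_polygons(
      deployment$release_longitude, deployment$release_latitude,
      polygons, buffer_m
    ))
  }
  if (!is.null(first_det) && nrow(first_det) > 0 &&
      !is.na(deployment$release_longitude) &&
      !is.na(deployment$release_latitude)) {
    d <- great_circle_distance(
      deployment$release_longitude, deployment$release_latitude,
      first_det$longitude[1], first_det$latitude[1]
    )
    checks <- c(checks, d <= radius_m)
  }
  if (length(checks) == 0) return(3L)
  if (any(checks)) 1L else 2L
}

#' Composite detection validity flag
#'
#' Counts how many of the five component tests (FDA, Distance, Velocity,
#' DetectionDistribution, DistanceRelease) passed with flag 1:
#' 5 passes gives Detection_QC 1 (valid), 4 gives 2 (likely valid), 3 gives 3
#' (likely invalid) and 2 or fewer gives 4 (invalid). A "test not performed"
#' flag (3) counts as not passed.
#'
#' @param fda,distance,velocity,distribution,distance_release Component flag
#'   vectors (recycled to a common length).
#' @return Integer vector of Detection_QC values in 1--4.
#' @export
composite_flag <- function(fda, distance, velocity, distribution,
                           distance_release) {
  n <- max(length(fda), length(distance), length(velocity),
           length(distribution), length(distance_release))
  comp <- cbind(
    rep_len(as.integer(fda), n), rep_len(as.integer(distance), n),
    rep_len(as.integer(velocity), n), rep_len(as.integer(distribution), n),
    rep_len(as.integer(distance_release), n)
  )
  if (any(is.na(comp)) ||
      any(!comp[, c(1, 2, 3, 5)] %in% c(1L, 2L)) ||
      any(!comp[, 4] %in% c(1L, 2L, 3L))) {
    stop("component flag outside its value set")
  }
  n1 <- rowSums(comp == 1L)
  out <- ifelse(n1 == 5, 1L, ifelse(n1 == 4, 2L, ifelse(n1 == 3, 3L, 4L)))
  as.integer(out)
}
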