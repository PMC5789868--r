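#' Run the full QC battery on one tag deployment
#'
#' Applies, in order: sensor conversion, the false-detection algorithm,
#' neighbour distance/speed metrics, the distance and velocity tests, the
#' species-distribution test, the distance-from-release test, the
#' release-date test, the release-location test, and the composite flag.
#'
#' @param deployment One deployment row from [read_tag_metadata()].
#' @param det That deployment's detections (any row order; re-sorted
#'   canonically).
#' @param stations Station registry ([read_stations()]).
#' @param surface A [build_cost_surface()] object.
#' @param distributions Named list of species distribution polygon sets
#'   (names are scientific names); a species absent from the list gets
#'   "test not performed" flags.
#' @param config A [qc_config()].
#' @param cache Optional [new_trip_cache()] shared across deployments.
#' @return A list with `qc` (the detections plus the seven component flags
#'   and Detection_QC, in canonical order) and `log` (per-deployment
#'   diagnostic record: flag counts and the fraction of detections with
#'   Detection_QC of 1 or 2).
#' @export
qc_deployment <- function(deployment, det, stations, surface,
                          distributions = list(), config = qc_config(),
                          cache = NULL) {
  # chronological order (station, then transmitter, as deterministic
  # tie-breaks): a dual-sensor tag's two transmitter streams are aggregated
  # into one time series for the movement tests
  o <- order(det$detection_timestamp, det$station_name, det$transmitter_id,
             method = "radix")
  det <- det[o, , drop = FALSE]
  rownames(det) <- NULL
  det <- apply_sensor_conversion(det, deployment)
  polygons <- distributions[[deployment$scientific_name]]

  fda <- fda_test(det, config)
  metrics <- neighbour_metrics(det, stations, surface, cache, config)
  dist_flag <- distance_test(metrics, config)
  vel_flag <- velocity_test(metrics, config)
  distr_flag <- distribution_test(det, polygons, config$distribution_buffer_m)
  rel_dist_flag <- distance_release_test(det, deployment,
                                         config$release_radius_m)
  rel_date_flag <- release_date_test(det, deployment,
                                     config$release_date_grace_s)
  rel_loc_flag <- release_location_test(
    deployment,
    if (nrow(det) > 0) det[1, , drop = FALSE] else NULL,
    polygons, config$release_radius_m, config$distribution_buffer_m
  )

  qc <- det
  qc$FDA_QC <- fda
  qc$Velocity_QC <- vel_flag
  qc$Distance_QC <- dist_flag
  qc$DetectionDistribution_QC <- distr_flag
  qc$DistanceRelease_QC <- rel_dist_flag
  qc$ReleaseDate_QC <- rel_date_flag
  qc$ReleaseLocation_QC <- rep(rel_loc_flag, nrow(det))
  qc$Detection_QC <- if (nrow(det) > 0) {
    composite_flag(fda, dist_flag, vel_flag, distr_flag, rel_dist_flag)
  } else integer(0)

  flag_fail_counts <- c(
    FDA_QC = sum(fda == 2L),
    Velocity_QC = sum(vel_flag == 2L),
    Distance_QC = sum(dist_flag == 2L),
    DetectionDistribution_QC = sum(distr_flag == 2L),
    DistanceRelease_QC = sum(rel_dist_flag == 2L),
    ReleaseDate_QC = sum(rel_date_flag == 2L)
  )
  log <- list(
    tag_id = deployment$tag_id,
    release_id = deployment$release_id,
    transmitter_ids = paste(deployment$transmitter_ids[[1]], collapse = ";"),
    scientific_name = deployment$scientific_name,
    n_detections = nrow(det),
    fail_counts = flag_fail_counts,
    release_location_flag = rel_loc_flag,
    composite_counts = vapply(1:4, function(k) sum(qc$Detection_QC == k),
                              integer(1)),
    frac_valid = if (nrow(det) > 0) mean(qc$Detection_QC <= 2L) else NA_real_
  )
  list(qc = qc, log = log)
}
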