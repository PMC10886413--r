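# End-to-end pipeline: calibrate -> reconstruct -> synchronize -> toe
# correction -> angles / cycles -> agreement report, with provenance
# embedded in every output file.

default_run_config <- function() {
  list(technique = "G3", rate = 100,
       cutoff_2d = 12, cutoff_3d = 6,
       n_cycles = 10, n_samples = 101,
       confidence_threshold = 0.6, max_missing_frac = 0.2,
       pole_marker = "RPOL3", output_dir = NULL)
}

resolve_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_skate("config file not found: %s", config, class = "io_error")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  for (f in c("keypoints", "markers", "calibration_points"))
    if (is.null(cfg[[f]]))
      stop_skate("run config is missing required field '%s'", f,
                 class = "config_error")
  cfg
}

hash_file <- function(path) unname(tools::md5sum(path))

hash_config <- function(cfg) {
  cfg$output_dir <- NULL  # where results go does not change what they are
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  hash_file(tmp)
}

#' Run the full markerless vs marker-based comparison pipeline
#'
#' Stages, in order: DLT calibration from the calibration point file; 3D
#' reconstruction of the markerless keypoints (12 Hz pixel filter,
#' triangulation, 6 Hz 3D filter); marker-based joint centers (6 Hz filter,
#' midpoint / Bell constructions); pole-strike detection in both systems
#' and integer-frame synchronization on the first strike; static
#' toe-placement correction; cycle segmentation and time normalization on
#' the marker-derived strike events (the cycle definition both systems
#' share); agreement report.  A failure in any stage leaves earlier
#' artifacts in place and reports the failing stage.
#'
#' @param config a named list or the path of a YAML file.  Required fields:
#'   `keypoints` (named list camera -> CSV path), `markers` (TRC path),
#'   `calibration_points` (CSV/JSON path).  Optional: `static_keypoints`,
#'   `static_markers` (enable the toe correction), `technique`, `rate`,
#'   `cutoff_2d` (12), `cutoff_3d` (6), `n_cycles` (10), `n_samples` (101),
#'   `confidence_threshold` (0.6), `max_missing_frac` (0.2), `pole_marker`
#'   (`"RPOL3"`), `output_dir` (write artifacts when set).
#' @return (invisibly) a list with the `report` ([build_report()]), the
#'   calibrations, trajectories, strike events and the resolved config.
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_skate("pipeline stage '%s' failed: %s", name, conditionMessage(e),
                 class = "pipeline_stage_error")
    })
  }

  inputs <- c(unlist(cfg$keypoints), cfg$markers, cfg$calibration_points,
              unlist(cfg$static_keypoints), cfg$static_markers)
  for (p in inputs)
    if (!file.exists(p))
      stop_skate("input file not found: %s", p, class = "io_error")

  calibs <- stage("calibrate", {
    cps <- read_calibration_points(cfg$calibration_points)
    lapply(names(cfg$keypoints), function(cam) estimate_dlt(cps, cam))
  })
  names(calibs) <- names(cfg$keypoints)

  ml <- stage("reconstruct", {
    kp <- lapply(cfg$keypoints, read_keypoints_2d, rate = cfg$rate)
    reconstruct_trial(kp, calibs, cutoff_2d = cfg$cutoff_2d,
                      cutoff_3d = cfg$cutoff_3d,
                      conf_threshold = cfg$confidence_threshold,
                      max_missing_frac = cfg$max_missing_frac)
  })

  mbdat <- stage("markers", {
    ms <- read_markers_trc(cfg$markers,
                           required_markers = c(unlist(default_marker_map()),
                                                "RASI", "LASI", "SACR",
                                                cfg$pole_marker))
    for (m in ms$markers)
      ms$data[, m, ] <- filter_columns_gapsafe(ms$data[, m, , drop = TRUE],
                                               cfg$cutoff_3d, cfg$rate)
    list(markers = ms, jc = joint_centers_from_markers(ms),
         pole_z = marker_xyz(ms, cfg$pole_marker)[, 3])
  })

  sync <- stage("synchronize", {
    strikes_ml <- detect_pole_strikes(point_xyz(ml, "pole_tip")[, 3], cfg$rate)
    strikes_mb <- detect_pole_strikes(mbdat$pole_z, cfg$rate)
    synchronize(point_xyz(ml, "pole_tip")[, 3], mbdat$pole_z,
                strikes_ml, strikes_mb)
  })
  ml$data <- ml$data[sync$frames_a, , , drop = FALSE]
  ml$residual <- ml$residual[sync$frames_a, , drop = FALSE]
  mb_jc <- mbdat$jc
  mb_jc$data <- mb_jc$data[sync$frames_b, , , drop = FALSE]
  strikes <- sync$events_b  # cycle definition: the right-pole markers

  toe_offset <- NULL
  if (!is.null(cfg$static_keypoints) && !is.null(cfg$static_markers)) {
    toe_offset <- stage("toe_offset", {
      kp_s <- lapply(cfg$static_keypoints, read_keypoints_2d, rate = cfg$rate)
      ml_s <- reconstruct_trial(kp_s, calibs, cutoff_2d = cfg$cutoff_2d,
                                cutoff_3d = cfg$cutoff_3d,
                                conf_threshold = cfg$confidence_threshold)
      ms_s <- read_markers_trc(cfg$static_markers)
      jc_s <- joint_centers_from_markers(ms_s)
      toe_offset_correction(ml_s, jc_s, rate = cfg$rate)
    })
    ml <- apply_toe_offset(ml, toe_offset)
  }

  res <- stage("cycles", {
    ml_jc <- list(rate = ml$rate,
                  data = ml$data[, JOINT_POINTS, , drop = FALSE])
    class(ml_jc) <- "joint_centers"
    list(ml = list(points = segment_cycles(ml_jc, strikes, cfg$technique,
                                           cfg$n_cycles, cfg$n_samples),
                   angles = segment_cycles(joint_vector_angles(ml_jc), strikes,
                                           cfg$technique, cfg$n_cycles,
                                           cfg$n_samples)),
         mb = list(points = segment_cycles(mb_jc, strikes, cfg$technique,
                                           cfg$n_cycles, cfg$n_samples),
                   angles = segment_cycles(joint_vector_angles(mb_jc), strikes,
                                           cfg$technique, cfg$n_cycles,
                                           cfg$n_samples)))
  })
  report <- stage("report", build_report(res$ml, res$mb, cfg$technique))

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(tool = "skate3d",
                 version = as.character(utils::packageVersion("skate3d")),
                 config_hash = hash_config(cfg))
    for (p in inputs) prov[[paste0("input_", basename(p))]] <- hash_file(p)
    write_dlt_json(calibs, file.path(cfg$output_dir, "calibration.json"))
    write_markers_trc(new_markerset3d(ml$rate, ml$data),
                      file.path(cfg$output_dir, "markerless_traj.trc"))
    write_report(report, json = file.path(cfg$output_dir, "report.json"),
                 distances_csv = file.path(cfg$output_dir, "distances.csv"),
                 angles_csv = file.path(cfg$output_dir, "angles.csv"),
                 provenance = prov)
    yaml::write_yaml(c(cfg[order(names(cfg))], list(provenance = prov)),
                     file.path(cfg$output_dir, "resolved_config.yaml"))
  }

  invisible(list(report = report, calibrations = calibs, markerless = ml,
                 markerbased = mb_jc, strikes = strikes, lag = sync$lag,
                 toe_offset = toe_offset, cycles = res, config = cfg))
}
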