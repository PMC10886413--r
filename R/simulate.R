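# Synthetic skier sessions.
#
# The simulator generates a band-limited periodic skeleton for one skier on
# a treadmill (right-side joints, pole tip, ski tip), projects it through
# ideal pinhole cameras expressed as DLT coefficient vectors (so the fitted
# model class contains the generating cameras exactly), and derives a
# marker-based counterpart whose midpoint / Bell constructions recover the
# true joint centers exactly at zero noise.  Controlled error terms:
#   * white pixel noise on the 2D keypoints (per-frame detection jitter);
#   * a smooth cycle-locked pixel error component (slowly varying detection
#     bias, the part of pose-estimation error that low-pass filtering
#     cannot remove);
#   * white marker noise plus a cycle-locked sinusoidal soft-tissue
#     artifact on the markers;
#   * a fixed toe-marker placement offset, recoverable from a static trial.
# With every noise term at zero the whole pipeline is an exact chain.

SIM_POINTS <- c(JOINT_POINTS, "pole_tip", "ski_tip")

#' Simulation configuration
#'
#' @param technique `"G1"` (one pole impact per cycle) or `"G3"` (two).
#' @param n_cycles number of skiing cycles (default 20 for G1, 15 for G3).
#' @param cycle_duration seconds per cycle (default 1.5 for G1, 1.2 for G3,
#'   matching roughly 30 s trials).
#' @param rate sampling rate in Hz (both systems run at 100 Hz).
#' @param cameras list of camera descriptions (`id`, `position`, `target`,
#'   `f_px`, `principal`); the default pair sits to the right of the
#'   treadmill: a perpendicular side camera at 1.05 m height and 2.0 m
#'   distance, and an oblique 45-degree camera at 2.5 m height and 1.9 m
#'   distance, both 1280 x 720.
#' @param pixel_noise_sd white pixel-noise SD in px (default 2, the scale
#'   of the 2D model test errors the pipeline is designed around).
#' @param pixel_bias_amp amplitude (px) of the smooth cycle-locked pixel
#'   error component (default 1.5; set 0 for white-noise-only keypoints).
#' @param marker_noise_sd white marker noise SD in mm (default 1).
#' @param soft_tissue_amp amplitude bound of the cycle-locked soft-tissue
#'   marker displacement in mm (default 20, the displacement scale
#'   reported for skin markers).
#' @param static_toe_offset fixed toe-marker placement offset (boot-top
#'   mounting) in mm, c(x, y, z).
#' @param sync_lag_frames non-negative integer: the marker-based recording
#'   starts this many frames before the video recording.
#' @param static_duration quiet-standing static trial length in seconds.
#' @param resolution declared camera resolution c(width, height).
#' @param seed integer seed fixing all randomness.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(technique = c("G3", "G1"), n_cycles = NULL,
                       cycle_duration = NULL, rate = 100,
                       cameras = default_cameras(),
                       pixel_noise_sd = 2, pixel_bias_amp = 1.5,
                       marker_noise_sd = 1, soft_tissue_amp = 20,
                       static_toe_offset = c(0, 30, 40),
                       sync_lag_frames = 0, static_duration = 2,
                       resolution = c(1280, 720), seed = 1) {
  technique <- match.arg(technique)
  n_cycles <- n_cycles %||% if (technique == "G1") 20 else 15
  cycle_duration <- cycle_duration %||% if (technique == "G1") 1.5 else 1.2
  cfg <- list(technique = technique, n_cycles = n_cycles,
              cycle_duration = cycle_duration, rate = rate, cameras = cameras,
              pixel_noise_sd = pixel_noise_sd, pixel_bias_amp = pixel_bias_amp,
              marker_noise_sd = marker_noise_sd,
              soft_tissue_amp = soft_tissue_amp,
              static_toe_offset = static_toe_offset,
              sync_lag_frames = as.integer(sync_lag_frames),
              static_duration = static_duration,
              resolution = resolution, seed = as.integer(seed))
  if (any(c(pixel_noise_sd, pixel_bias_amp, marker_noise_sd,
            soft_tissue_amp) < 0))
    stop_skate("noise amplitudes must be >= 0", class = "config_error")
  if (rate <= 0) stop_skate("rate must be positive", class = "config_error")
  if (length(cameras) < 2)
    stop_skate("at least two cameras required", class = "config_error")
  if (cycle_duration * rate < 20)
    stop_skate("resolution error: %g s cycles at %g Hz give < 20 frames per cycle",
               cycle_duration, rate, class = "config_error")
  if (cfg$sync_lag_frames < 0)
    stop_skate("sync_lag_frames must be >= 0", class = "config_error")
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_cameras <- function() {
  list(list(id = "cam0", position = c(4.70, 1.75, 1.05),
            target = c(1.5, 1.75, 1.0), f_px = 700, principal = c(640, 360)),
       list(id = "cam1", position = c(4.04, 0.41, 2.50),
            target = c(1.5, 1.75, 1.0), f_px = 550, principal = c(640, 360)))
}

# number of pole impacts per cycle
impacts_per_cycle <- function(technique) if (technique == "G3") 2L else 1L

# dynamic skeleton at arbitrary times (seconds); returns length(t) x 9 x 3
#
# The trunk and arm coordinates are single sinusoids (at the cycle and
# poling frequencies respectively) and the legs are a sagittal
# segment-angle chain driven by single sinusoids, so the spectrum decays
# like Bessel coefficients and the trajectories are band-limited below
# about 3 Hz for the default cycle durations.  Joint vector angle ranges:
# knee about 12-88 degrees, elbow 27-128, shoulder 14-63, hip 14-48,
# ankle -7..17, all clear of the 0/180-degree degeneracies.
skeleton_dynamic <- function(t, config) {
  w <- 2 * pi / config$cycle_duration           # leg / cycle frequency
  ipc <- impacts_per_cycle(config$technique)
  wa <- ipc * w                                 # arm / pole frequency
  Tp <- config$cycle_duration / ipc

  d2r <- pi / 180
  hip <- cbind(1.45 + 0.02 * sin(w * t + 0.4),
               1.75 + 0.06 * sin(w * t),
               0.98 + 0.03 * sin(w * t + 0.7))
  # legs: sagittal segment-angle chain (thigh tilt, knee flexion, foot
  # pitch), so the knee vector angle spans ~12-88 degrees by construction
  th_t <- (20 + 25 * sin(w * t + 0.3)) * d2r
  kappa <- (50 + 38 * sin(w * t + 1.2)) * d2r
  knee <- hip + cbind(0.012 + 0.010 * sin(w * t + 2.5),
                      0.44 * sin(th_t), -0.44 * cos(th_t))
  th_s <- th_t - kappa
  ankle <- knee + cbind(0.005 * sin(w * t + 1.0),
                        0.43 * sin(th_s), -0.43 * cos(th_s))
  psi_f <- (95 + 12 * sin(w * t + 2.0)) * d2r
  toe <- ankle + cbind(0.004 * sin(w * t + 0.2),
                       0.17 * sin(th_s + psi_f), -0.17 * cos(th_s + psi_f))

  # arms: single-harmonic coordinates at the poling frequency (the
  # amplitudes keep the elbow vector angle within ~30-130 degrees, clear
  # of the collinear degeneracy)
  shoulder <- cbind(1.52 + 0.010 * sin(wa * t + 0.3),
                    1.80 + 0.040 * sin(wa * t + 0.8),
                    1.44 + 0.020 * sin(w * t + 1.5))
  elbow <- shoulder + cbind(0.012 + 0.008 * sin(wa * t + 2.1),
                            0.107 + 0.196 * sin(wa * t + 5.570),
                            -0.199 + 0.153 * sin(wa * t + 2.578))
  wrist <- elbow + cbind(0.008 * sin(wa * t + 0.6),
                         0.143 + 0.122 * sin(wa * t + 0.752),
                         -0.060 + 0.121 * sin(wa * t + 4.371))

  # pole tip: contact (z = 0) windows centered on (m + 0.5) * Tp
  cphase <- abs(cos(pi * t / Tp))
  cclip <- 0.08
  pole_z <- 0.55 * pmax(0, cphase - cclip) / (1 - cclip)
  pole <- cbind(1.60 + 0.01 * sin(wa * t),
                1.75 + 0.25 * cos(2 * pi * t / Tp + 0.6),
                pole_z)
  ski <- cbind(1.56 + 0.02 * sin(w * t + 0.5),
               2.30 + 0.25 * sin(w * t + 1.9),
               0.035 + 0.035 * sin(w * t + 2.8))

  arr <- array(NA_real_, c(length(t), length(SIM_POINTS), 3),
               dimnames = list(NULL, SIM_POINTS, c("x", "y", "z")))
  arr[, "wrist", ] <- wrist; arr[, "elbow", ] <- elbow
  arr[, "shoulder", ] <- shoulder; arr[, "hip", ] <- hip
  arr[, "knee", ] <- knee; arr[, "ankle", ] <- ankle
  arr[, "toe", ] <- toe; arr[, "pole_tip", ] <- pole
  arr[, "ski_tip", ] <- ski
  arr
}

# quiet-standing pose (constant in time)
skeleton_static <- function(t, config) {
  d2r <- pi / 180
  hip <- c(1.45, 1.75, 0.99)
  th_t <- 5 * d2r; kappa <- 8 * d2r; th_s <- th_t - kappa; psi_f <- 95 * d2r
  knee <- hip + c(0.01, 0.44 * sin(th_t), -0.44 * cos(th_t))
  ankle <- knee + c(0.005, 0.43 * sin(th_s), -0.43 * cos(th_s))
  toe <- ankle + c(0.004, 0.17 * sin(th_s + psi_f), -0.17 * cos(th_s + psi_f))
  shoulder <- c(1.52, 1.80, 1.44)
  th_u <- -10 * d2r; eps <- 30 * d2r
  elbow <- shoulder + c(0.01, 0.30 * sin(th_u), -0.30 * cos(th_u))
  wrist <- elbow + c(0.008, 0.27 * sin(th_u + eps), -0.27 * cos(th_u + eps))
  pose <- rbind(wrist, elbow, shoulder, hip, knee, ankle, toe,
                c(1.60, 1.90, 0.30), c(1.56, 2.30, 0.035))
  arr <- array(NA_real_, c(length(t), length(SIM_POINTS), 3),
               dimnames = list(NULL, SIM_POINTS, c("x", "y", "z")))
  for (p in seq_along(SIM_POINTS)) arr[, p, ] <- rep(pose[p, ], each = length(t))
  arr
}

# first frame of each z == 0 contact run
contact_starts <- function(z, eps = 1e-12) {
  contact <- z <= eps
  which(contact & !c(FALSE, contact[-length(contact)]))
}

#' Simulate ground-truth skier kinematics
#'
#' Generates the true joint-center trajectories (seven joints plus pole tip
#' and ski tip), the true pole-strike frames, the true joint vector angles
#' (computed with [joint_vector_angles()], so simulator and pipeline share
#' one angle definition), and the true DLT coefficient vectors of the
#' configured cameras.  The skeleton is a low-order Fourier construction:
#' periodic, band-limited, with plausible ranges (knee vector angle
#' oscillating roughly 10-90 degrees), not a biomechanically validated
#' model.  Fully deterministic: the trajectory itself carries no noise.
#'
#' @param config a [sim_config()].
#' @return a `ground_truth` list: `rate`, `time`, `points` (frames x 9 x 3),
#'   `strikes`, `angles`, `calibrations`, `config`.
#' @export
simulate_skier <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  nf <- round(config$n_cycles * config$cycle_duration * config$rate)
  t <- (seq_len(nf) - 1) / config$rate
  pts <- skeleton_dynamic(t, config)
  strikes <- contact_starts(pts[, "pole_tip", "z"])
  calibs <- lapply(config$cameras, function(cam)
    structure(list(camera_id = cam$id,
                   L = dlt_from_pinhole(cam$position, cam$target, cam$f_px,
                                        cam$principal),
                   reprojection_rmse = 0, n_points = NA_integer_,
                   df_residual = NA_integer_, fitted_at = NA_character_),
              class = "dlt_calibration"))
  names(calibs) <- vapply(config$cameras, `[[`, character(1), "id")
  structure(list(rate = config$rate, time = t, points = pts,
                 strikes = strikes,
                 angles = joint_vector_angles(pts),
                 calibrations = calibs, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth (%s): %d frames @ %g Hz, %d cycles, %d pole strikes\n",
              x$config$technique, length(x$time), x$rate,
              x$config$n_cycles, length(x$strikes)))
  invisible(x)
}

# smooth cycle-locked pixel error field for one camera: frames x points x 2
pixel_bias_field <- function(t, npts, amp, w) {
  if (amp == 0) return(array(0, c(length(t), npts, 2)))
  out <- array(0, c(length(t), npts, 2))
  for (p in seq_len(npts)) for (d in 1:2) {
    ph <- runif(2, 0, 2 * pi)
    out[, p, d] <- amp * (0.75 * sin(w * t + ph[1]) +
                            0.25 * sin(2 * w * t + ph[2]))
  }
  out
}

#' Project ground truth to per-camera 2D keypoint trajectories
#'
#' Exact DLT projection plus the configured pixel error terms: white
#' Gaussian noise of SD `pixel_noise_sd` and a cycle-locked smooth error of
#' amplitude `pixel_bias_amp` (random phase per point, camera and axis).
#' Confidence is 1 unless a point projects behind a camera (occlusion),
#' which marks it missing with confidence 0.
#'
#' @param gt a `ground_truth` object.
#' @param config its [sim_config()] (defaults to the one stored in `gt`).
#' @param points optional frames x points x 3 array overriding `gt$points`
#'   (used for static trials).
#' @param seed_offset small integer added to `config$seed` so different
#'   trials draw independent noise while staying reproducible.
#' @return named list of `trajectory2d`, one per camera.
#' @export
project_to_cameras <- function(gt, config = gt$config, points = NULL,
                               seed_offset = 1) {
  pts <- points %||% gt$points
  nf <- dim(pts)[1]; npts <- dim(pts)[2]
  t <- (seq_len(nf) - 1) / config$rate
  w <- 2 * pi / config$cycle_duration
  set.seed(config$seed + seed_offset)
  out <- list()
  for (ci in seq_along(config$cameras)) {
    cam <- config$cameras[[ci]]
    L <- gt$calibrations[[cam$id]]$L
    u <- v <- conf <- matrix(NA_real_, nf, npts)
    bias <- pixel_bias_field(t, npts, config$pixel_bias_amp, w)
    for (p in seq_len(npts)) {
      xyz <- pts[, p, , drop = TRUE]
      if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
      den <- as.numeric(xyz %*% L[9:11]) + 1
      uv <- dlt_project(L, xyz)
      vis <- den > 1e-6
      u[, p] <- ifelse(vis, uv[, 1] + bias[, p, 1], NA_real_)
      v[, p] <- ifelse(vis, uv[, 2] + bias[, p, 2], NA_real_)
      conf[, p] <- as.numeric(vis)
    }
    if (config$pixel_noise_sd > 0) {
      u <- u + matrix(rnorm(nf * npts, 0, config$pixel_noise_sd), nf, npts)
      v <- v + matrix(rnorm(nf * npts, 0, config$pixel_noise_sd), nf, npts)
    }
    out[[cam$id]] <- new_trajectory2d(cam$id, config$rate, dimnames(pts)[[2]],
                                      u, v, conf,
                                      width = config$resolution[1],
                                      height = config$resolution[2])
  }
  out
}

# marker construction offsets (meters, relative to the true joint centers)
marker_offsets <- function() {
  list(RWRL = list("wrist", c(0.030, 0, 0)), RWRM = list("wrist", c(-0.030, 0, 0)),
       RELL = list("elbow", c(0.035, 0, 0)), RELM = list("elbow", c(-0.035, 0, 0)),
       RKNL = list("knee", c(0.050, 0, 0)), RKNM = list("knee", c(-0.050, 0, 0)),
       RANL = list("ankle", c(0.040, 0, 0)), RANM = list("ankle", c(-0.040, 0, 0)),
       RSHA = list("shoulder", c(0, 0.050, 0)), RSHP = list("shoulder", c(0, -0.050, 0)))
}

#' Derive the marker-based counterpart of a simulated trial
#'
#' Places lateral/medial, anterior/posterior and pelvis markers at fixed
#' offsets from the true joint centers so the midpoint and Bell
#' constructions recover the true centers exactly at zero noise; adds white
#' marker noise and a cycle-locked sinusoidal soft-tissue displacement
#' (fixed random direction and phase per marker, amplitude bounded by
#' `soft_tissue_amp`) to the skin and boot markers; displaces the toe
#' marker by `static_toe_offset` (boot-top mounting); and generates a
#' quiet-standing static trial with the same construction but no
#' soft-tissue motion.  If `sync_lag_frames > 0` the marker recording
#' starts that many frames before the video.
#'
#' @param gt a `ground_truth` object.
#' @param config its [sim_config()].
#' @return list with `markers` and `static_markers` (`markerset3d`), the
#'   `marker_map` for [joint_centers_from_markers()], and `pole_label`
#'   (the distal right-pole marker used for strike detection).
#' @export
derive_markerbased <- function(gt, config = gt$config) {
  rate <- config$rate
  lag <- config$sync_lag_frames
  nf <- dim(gt$points)[1] + lag
  t <- (seq_len(nf) - 1 - lag) / rate
  pts <- skeleton_dynamic(t, config)
  set.seed(config$seed + 11L)
  dyn <- build_markers(pts, t, config, soft_tissue = TRUE)
  ns <- round(config$static_duration * rate)
  ts <- (seq_len(ns) - 1) / rate
  stat_pts <- skeleton_static(ts, config)
  set.seed(config$seed + 12L)
  stat <- build_markers(stat_pts, ts, config, soft_tissue = FALSE)
  list(markers = dyn, static_markers = stat,
       marker_map = default_marker_map(), pole_label = "RPOL3")
}

build_markers <- function(pts, t, config, soft_tissue = TRUE) {
  nf <- length(t)
  offs <- marker_offsets()
  labels <- c(names(offs), "RASI", "LASI", "SACR", "RTOE",
              "RPOL1", "RPOL2", "RPOL3")
  arr <- array(NA_real_, c(nf, length(labels), 3),
               dimnames = list(NULL, labels, c("x", "y", "z")))
  for (m in names(offs))
    arr[, m, ] <- sweep(pts[, offs[[m]][[1]], , drop = TRUE], 2,
                        -offs[[m]][[2]])
  # pelvis cluster placed so the Bell construction inverts exactly:
  # world-aligned pelvis axes, inter-ASIS distance 0.24 m
  d <- 0.24
  bc <- bell_coefficients()
  hip <- pts[, "hip", , drop = TRUE]
  mid <- sweep(hip, 2, d * c(bc[["lateral"]], -bc[["posterior"]],
                             -bc[["inferior"]]))
  arr[, "RASI", ] <- sweep(mid, 2, -c(d / 2, 0, 0))
  arr[, "LASI", ] <- sweep(mid, 2, c(d / 2, 0, 0))
  arr[, "SACR", ] <- sweep(mid, 2, c(0, 0.13, 0))
  arr[, "RTOE", ] <- sweep(pts[, "toe", , drop = TRUE], 2,
                           -config$static_toe_offset / 1000)
  # rigid pole: markers along the shaft from the tip toward the grip
  shaft <- pts[, "wrist", , drop = TRUE] - pts[, "pole_tip", , drop = TRUE]
  shaft <- shaft / row_norm(shaft)
  for (i in 1:3)
    arr[, paste0("RPOL", i), ] <- pts[, "pole_tip", , drop = TRUE] +
      shaft * c(0.95, 0.50, 0.05)[i]
  # soft-tissue artifact: cycle-locked sinusoid, fixed direction and phase
  # per skin / boot marker (pole markers are rigid)
  soft_labels <- c(names(offs), "RASI", "LASI", "SACR", "RTOE")
  if (soft_tissue && config$soft_tissue_amp > 0) {
    w <- 2 * pi / config$cycle_duration
    amp <- config$soft_tissue_amp / 1000
    for (m in soft_labels) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ph <- runif(1, 0, 2 * pi)
      disp <- amp * sin(w * t + ph)
      arr[, m, ] <- arr[, m, , drop = TRUE] + outer(disp, dir)
    }
  }
  if (config$marker_noise_sd > 0)
    arr <- arr + array(rnorm(length(arr), 0, config$marker_noise_sd / 1000),
                       dim(arr))
  new_markerset3d(config$rate, arr)
}

#' Write a complete synthetic testing session to disk
#'
#' Produces a desk-scale replica of one session: per-camera dynamic and
#' static keypoint CSVs, dynamic and static marker TRC files, a calibration
#' point file (the eight corners of a 2 m cube with one corner at the
#' origin, digitized exactly through the true cameras), a ground-truth JSON
#' (strike frames, true DLT coefficients, configuration), and a pipeline
#' configuration YAML wired to all of them.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with the file `paths`, the `ground_truth` and
#'   the marker-based bundle.
#' @export
end_to_end_fixture <- function(config = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- simulate_skier(config)
  kp <- project_to_cameras(gt, config, seed_offset = 1)
  ns <- round(config$static_duration * config$rate)
  stat_pts <- skeleton_static((seq_len(ns) - 1) / config$rate, config)
  kp_static <- project_to_cameras(gt, config, points = stat_pts,
                                  seed_offset = 2)
  mb <- derive_markerbased(gt, config)

  paths <- list()
  for (cam in names(kp)) {
    paths[[paste0("kp_", cam)]] <- file.path(dir, paste0(cam, ".csv"))
    write_keypoints_2d(kp[[cam]], paths[[paste0("kp_", cam)]])
    paths[[paste0("kp_static_", cam)]] <- file.path(dir, paste0("static_", cam, ".csv"))
    write_keypoints_2d(kp_static[[cam]], paths[[paste0("kp_static_", cam)]])
  }
  paths$markers <- file.path(dir, "markers.trc")
  write_markers_trc(mb$markers, paths$markers, units = "mm")
  paths$static_markers <- file.path(dir, "static_markers.trc")
  write_markers_trc(mb$static_markers, paths$static_markers, units = "mm")

  corners <- as.matrix(expand.grid(X = c(0, 2), Y = c(0, 2), Z = c(0, 2)))
  cps <- calibration_points(
    data.frame(label = paste0("c", seq_len(nrow(corners))),
               X = corners[, 1], Y = corners[, 2], Z = corners[, 3]),
    lapply(gt$calibrations, function(cc) dlt_project(cc$L, corners)))
  paths$calibration <- file.path(dir, "calibration_points.csv")
  write_calibration_points(cps, paths$calibration)

  paths$ground_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(technique = config$technique, rate = config$rate,
         n_cycles = config$n_cycles, cycle_duration = config$cycle_duration,
         strikes = gt$strikes,
         calibrations = lapply(gt$calibrations, `[[`, "L"),
         seed = config$seed),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  paths$config <- file.path(dir, "run.yaml")
  run_cfg <- list(
    technique = config$technique, rate = config$rate,
    keypoints = stats::setNames(
      lapply(names(kp), function(cam) file.path(dir, paste0(cam, ".csv"))),
      names(kp)),
    static_keypoints = stats::setNames(
      lapply(names(kp), function(cam) file.path(dir, paste0("static_", cam, ".csv"))),
      names(kp)),
    markers = paths$markers, static_markers = paths$static_markers,
    calibration_points = paths$calibration,
    cutoff_2d = 12, cutoff_6d = NULL, cutoff_3d = 6,
    n_cycles = 10, n_samples = 101, confidence_threshold = 0.6,
    output_dir = file.path(dir, "out"))
  run_cfg$cutoff_6d <- NULL
  yaml::write_yaml(run_cfg, paths$config)
  invisible(list(paths = paths, ground_truth = gt, markerbased = mb,
                 keypoints = kp, static_keypoints = kp_static))
}
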