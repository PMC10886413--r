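# Markerless reconstruction chain.
#
# Fixed order of operations, mirroring the laboratory processing:
#   1. 4th-order zero-phase Butterworth at 12 Hz on the pixel coordinates,
#   2. per-frame, per-point DLT triangulation across the cameras,
#   3. 4th-order zero-phase Butterworth at 6 Hz on the 3D coordinates.
# Frames where fewer than two cameras see a point confidently are marked
# missing, never interpolated; a trial is rejected when too large a
# fraction of frames is unusable for a required point.

# filter each column; internal gaps are bridged by linear interpolation for
# the filter pass only and re-masked afterwards, so missing frames stay
# missing downstream
filter_columns_gapsafe <- function(m, cutoff, rate) {
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    bad <- !is.finite(v)
    if (all(bad)) next
    if (any(bad)) {
      idx <- seq_along(v)
      v <- approx(idx[!bad], v[!bad], xout = idx, rule = 2)$y
    }
    v <- filter_lowpass(v, cutoff, rate)
    v[bad] <- NA_real_
    m[, j] <- v
  }
  m
}

#' Reconstruct a 3D trial from synchronized multi-camera keypoints
#'
#' @param kp list of `trajectory2d` objects, one per camera, frame-aligned
#'   (the two video cameras are recorded by one system and share a clock).
#' @param calibs list of `dlt_calibration`, matching `kp` by position or by
#'   camera id.
#' @param cutoff_2d pixel-coordinate filter cutoff in Hz (default 12).
#' @param cutoff_3d 3D-coordinate filter cutoff in Hz (default 6).
#' @param conf_threshold minimum keypoint confidence (default 0.6).
#' @param max_missing_frac maximum tolerated fraction of unusable frames
#'   per required point before the trial is rejected (default 0.2).
#' @param required_points points checked against `max_missing_frac`
#'   (default: all).
#' @return a `trajectory3d` (meters, treadmill frame) with per-frame,
#'   per-point RMS pixel residuals.
#' @export
reconstruct_trial <- function(kp, calibs, cutoff_2d = 12, cutoff_3d = 6,
                              conf_threshold = 0.6, max_missing_frac = 0.2,
                              required_points = NULL) {
  stopifnot(length(kp) >= 1, length(kp) == length(calibs))
  if (!is.null(names(calibs)) && !is.null(names(kp)) &&
      all(names(kp) %in% names(calibs)))
    calibs <- calibs[names(kp)]
  pts <- kp[[1]]$points
  rate <- kp[[1]]$rate
  for (tr in kp)
    if (!identical(tr$points, pts) || tr$rate != rate)
      stop_skate("cameras disagree on point labels or rate", class = "format_error")
  nf <- min(vapply(kp, function(tr) nrow(tr$u), integer(1)))

  ncam <- length(kp)
  u <- v <- conf <- array(NA_real_, c(nf, length(pts), ncam))
  for (ci in seq_len(ncam)) {
    u[, , ci] <- filter_columns_gapsafe(kp[[ci]]$u[seq_len(nf), , drop = FALSE],
                                        cutoff_2d, rate)
    v[, , ci] <- filter_columns_gapsafe(kp[[ci]]$v[seq_len(nf), , drop = FALSE],
                                        cutoff_2d, rate)
    conf[, , ci] <- kp[[ci]]$confidence[seq_len(nf), , drop = FALSE]
  }

  xyz <- array(NA_real_, c(nf, length(pts), 3),
               dimnames = list(NULL, pts, c("x", "y", "z")))
  resid <- matrix(NA_real_, nf, length(pts), dimnames = list(NULL, pts))
  for (p in seq_along(pts)) {
    tri <- triangulate_series(u[, p, , drop = TRUE], v[, p, , drop = TRUE],
                              conf[, p, , drop = TRUE], calibs,
                              conf_threshold = conf_threshold)
    xyz[, p, ] <- tri$xyz
    resid[, p] <- tri$residual
  }

  required_points <- required_points %||% pts
  miss <- colMeans(!is.finite(xyz[, , 1, drop = TRUE]))
  bad <- miss[required_points] > max_missing_frac
  if (any(bad))
    stop_skate(
      "trial rejected: point(s) %s unusable on more than %.0f%% of frames (worst %.0f%%)",
      paste(required_points[bad], collapse = ", "), 100 * max_missing_frac,
      100 * max(miss[required_points]), class = "data_quality_error")
  if (any(miss > 0))
    message(sprintf("reconstruct_trial: %d point-frames missing (< 2 usable cameras)",
                    sum(!is.finite(xyz[, , 1]))))

  for (p in seq_along(pts))
    xyz[, p, ] <- filter_columns_gapsafe(xyz[, p, , drop = TRUE], cutoff_3d, rate)
  new_trajectory3d(rate, xyz, resid)
}
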