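# Joint centers and joint vector angles.
#
# Marker-based joint centers: wrist, elbow, knee and ankle are midpoints of
# lateral/medial marker pairs; the shoulder is the midpoint of anterior and
# posterior markers; the hip joint center follows the Bell regression,
# offset from the inter-ASIS midpoint by fixed fractions of the inter-ASIS
# distance along the pelvis axes; the toe is the toe marker itself.
# Markerless joint centers are the detected keypoints, which were labeled
# directly on the joint centers, so no further modeling is applied there.
#
# Joint vector angles are simplified proxies computed from three joint
# centers each: the elbow, hip and knee angles are the supplement of the
# angle between the two vectors joining the apex to its neighbors, the
# shoulder angle is the raw vector angle, and the ankle angle the
# complement.

JOINT_POINTS <- c("wrist", "elbow", "shoulder", "hip", "knee", "ankle", "toe")
ANGLE_NAMES <- c("elbow", "shoulder", "hip", "knee", "ankle")

default_marker_map <- function() {
  list(wrist = c("RWRL", "RWRM"), elbow = c("RELL", "RELM"),
       knee = c("RKNL", "RKNM"), ankle = c("RANL", "RANM"),
       shoulder = c("RSHA", "RSHP"), toe = "RTOE")
}

#' Bell hip-joint-center regression coefficients
#'
#' Offsets of the hip joint center from the inter-ASIS midpoint as
#' fractions of the inter-ASIS distance, along the pelvis lateral,
#' posterior and inferior axes.  These are configuration data, exposed so
#' that alternative regression variants can be used.
#'
#' @export
bell_coefficients <- function() c(lateral = 0.36, posterior = 0.19, inferior = 0.30)

# pelvis frame from ASIS + sacrum markers; returns hip center(s), frames x 3
bell_hip_center <- function(rasi, lasi, sacr, coef = bell_coefficients(),
                            side = "right") {
  rasi <- as_matrix3(rasi); lasi <- as_matrix3(lasi); sacr <- as_matrix3(sacr)
  mid <- (rasi + lasi) / 2
  d <- row_norm(rasi - lasi)
  xhat <- (rasi - lasi) / d                     # toward the right
  ant <- mid - sacr
  ant <- ant - xhat * rowSums(ant * xhat)
  yhat <- ant / row_norm(ant)                   # anterior
  zhat <- row_cross(xhat, yhat)                 # superior (right-handed)
  lat <- if (side == "right") coef[["lateral"]] else -coef[["lateral"]]
  mid + d * (lat * xhat - coef[["posterior"]] * yhat - coef[["inferior"]] * zhat)
}

#' Compute reference joint centers from a 3D marker set
#'
#' @param markers a `markerset3d` of the dynamic trial (meters).
#' @param marker_map named list mapping each of wrist/elbow/knee/ankle/
#'   shoulder to its marker pair and toe to its marker; defaults to the
#'   right-side labels used by the simulator.
#' @param bell regression coefficients, see [bell_coefficients()].
#' @param pelvis_labels labels of the right ASIS, left ASIS and sacrum
#'   markers used for the Bell hip-center construction.
#' @return an object of class `joint_centers`: frames x 7 x 3 array
#'   (`wrist`, `elbow`, `shoulder`, `hip`, `knee`, `ankle`, `toe`) plus the
#'   sampling rate.  Frames with a masked (gap) defining marker come back
#'   `NA` for the affected joint.
#' @export
joint_centers_from_markers <- function(markers,
                                       marker_map = default_marker_map(),
                                       bell = bell_coefficients(),
                                       pelvis_labels = c("RASI", "LASI", "SACR")) {
  stopifnot(inherits(markers, "markerset3d"))
  nf <- dim(markers$data)[1]
  out <- array(NA_real_, c(nf, length(JOINT_POINTS), 3),
               dimnames = list(NULL, JOINT_POINTS, c("x", "y", "z")))
  for (j in c("wrist", "elbow", "knee", "ankle", "shoulder")) {
    pair <- marker_map[[j]]
    out[, j, ] <- (marker_xyz(markers, pair[1]) + marker_xyz(markers, pair[2])) / 2
  }
  out[, "toe", ] <- marker_xyz(markers, marker_map$toe)
  absent <- setdiff(pelvis_labels, markers$markers)
  if (length(absent) > 0)
    stop_skate("hip center unavailable: missing pelvis markers %s",
               paste(absent, collapse = ", "), class = "marker_missing_error")
  out[, "hip", ] <- bell_hip_center(marker_xyz(markers, pelvis_labels[1]),
                                    marker_xyz(markers, pelvis_labels[2]),
                                    marker_xyz(markers, pelvis_labels[3]),
                                    coef = bell)
  structure(list(rate = markers$rate, data = out), class = "joint_centers")
}

#' @export
print.joint_centers <- function(x, ...) {
  cat(sprintf("Joint centers: %d frames x %d points @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], x$rate))
  invisible(x)
}

# coerce trajectory3d / joint_centers / array to a frames x points x 3 array
# restricted to the seven joint points
joint_array <- function(x) {
  arr <- if (inherits(x, "trajectory3d")) x$data
         else if (inherits(x, "joint_centers")) x$data
         else x
  missing <- setdiff(JOINT_POINTS, dimnames(arr)[[2]])
  if (length(missing) > 0)
    stop_skate("joint points missing: %s", paste(missing, collapse = ", "),
               class = "label_error")
  arr[, JOINT_POINTS, , drop = FALSE]
}

#' Static toe-placement offset between systems
#'
#' The marker-based toe marker sits on top of the skiing boot while the
#' markerless keypoint is the boot tip, so the two systems see the toe at
#' systematically different places.  A quiet-standing static trial is used
#' to estimate that fixed offset, which is then added to the markerless toe
#' in dynamic trials before any comparison.
#'
#' @param static_markerless markerless static toe positions: a
#'   `trajectory3d`, `joint_centers`, or frames x 3 matrix (meters).
#' @param static_markerbased marker-based counterpart, same options.
#' @param rate sampling rate in Hz (needed for the minimum-duration check
#'   when plain matrices are passed).
#' @param min_duration minimum static span in seconds (default 1).
#' @return named offset vector (x, y, z) in meters: marker-based toe minus
#'   markerless toe, averaged over the static frames; the frame count is
#'   attached as attribute `n_frames`.
#' @export
toe_offset_correction <- function(static_markerless, static_markerbased,
                                  rate = NULL, min_duration = 1) {
  toe_of <- function(x) {
    if (inherits(x, c("trajectory3d", "joint_centers")))
      x <- if (inherits(x, "trajectory3d")) point_xyz(x, "toe") else x$data[, "toe", ]
    as_matrix3(x)
  }
  rate <- rate %||%
    (if (!is.null(static_markerless$rate)) static_markerless$rate else NA_real_)
  ml <- toe_of(static_markerless)
  mb <- toe_of(static_markerbased)
  n <- min(nrow(ml), nrow(mb))
  if (!is.na(rate) && n < min_duration * rate)
    stop_skate("static trial too short: %d frames < %g s at %g Hz",
               n, min_duration, rate, class = "static_too_short_error")
  off <- colMeans(mb[seq_len(n), , drop = FALSE] -
                    ml[seq_len(n), , drop = FALSE], na.rm = TRUE)
  structure(stats::setNames(off, c("x", "y", "z")), n_frames = n)
}

#' Apply a toe offset to a trajectory
#'
#' @param traj a `trajectory3d` or `joint_centers` object.
#' @param offset offset vector from [toe_offset_correction()].
#' @return the object with the offset added to its `toe` point.
#' @export
apply_toe_offset <- function(traj, offset) {
  arr <- if (inherits(traj, "trajectory3d")) traj$data else traj$data
  arr[, "toe", ] <- sweep(arr[, "toe", , drop = TRUE], 2, -as.numeric(offset))
  traj$data <- arr
  traj
}

# angle (degrees) between row vectors a and b via atan2(|a x b|, a.b),
# stable near 0 and 180 degrees
vector_angle_deg <- function(a, b) {
  cr <- row_cross(a, b)
  ang <- rad2deg(atan2(row_norm(cr), rowSums(a * b)))
  zero <- row_norm(a) == 0 | row_norm(b) == 0
  ang[zero] <- NA_real_
  ang
}

#' Joint vector angles from joint centers
#'
#' Computes the five joint vector angles (degrees) per frame:
#' \itemize{
#'   \item elbow: supplement of the angle between elbow-to-wrist and
#'     elbow-to-shoulder (0 deg = fully extended arm);
#'   \item shoulder: angle between shoulder-to-elbow and shoulder-to-hip
#'     (upper arm vs upper body);
#'   \item hip: supplement of the angle between hip-to-shoulder and
#'     hip-to-knee;
#'   \item knee: supplement of the angle between knee-to-hip and
#'     knee-to-ankle;
#'   \item ankle: complement of the angle between ankle-to-knee and
#'     ankle-to-toe.
#' }
#' Angles use the two-argument arctangent of the cross- and dot-products,
#' which is numerically stable near 0 and 180 degrees.  Frames with a
#' zero-length defining vector or a missing point come back `NA`.
#'
#' @param jc a `joint_centers` object, `trajectory3d`, or frames x points x
#'   3 array containing the seven joint points.
#' @return frames x 5 matrix (columns `elbow`, `shoulder`, `hip`, `knee`,
#'   `ankle`), class `angle_series`.
#' @export
joint_vector_angles <- function(jc) {
  arr <- joint_array(jc)
  g <- function(p) {
    m <- arr[, p, , drop = FALSE]
    dim(m) <- dim(m)[c(1, 3)]
    m
  }
  out <- cbind(
    elbow = 180 - vector_angle_deg(g("wrist") - g("elbow"),
                                   g("shoulder") - g("elbow")),
    shoulder = vector_angle_deg(g("elbow") - g("shoulder"),
                                g("hip") - g("shoulder")),
    hip = 180 - vector_angle_deg(g("shoulder") - g("hip"),
                                 g("knee") - g("hip")),
    knee = 180 - vector_angle_deg(g("hip") - g("knee"),
                                  g("ankle") - g("knee")),
    ankle = 90 - vector_angle_deg(g("knee") - g("ankle"),
                                  g("toe") - g("ankle")))
  class(out) <- c("angle_series", class(out))
  out
}
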