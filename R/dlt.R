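# Direct linear transformation (DLT) camera calibration and triangulation.
#
# The 11-parameter DLT maps a world point (X, Y, Z) in meters to pixel
# coordinates:
#
#   u = (L1 X + L2 Y + L3 Z + L4)  / (L9 X + L10 Y + L11 Z + 1)
#   v = (L5 X + L6 Y + L7 Z + L8)  / (L9 X + L10 Y + L11 Z + 1)
#
# which is the general projective pinhole camera with the scale of the
# third row fixed by the +1.  Calibration solves the stacked linear
# least-squares system (two equations per digitized point); triangulation
# inverts the same equations across two or more calibrated cameras.

dlt_to_P <- function(L) {
  matrix(c(L[1:4], L[5:8], L[9:11], 1), nrow = 3, byrow = TRUE)
}

P_to_dlt <- function(P) {
  P <- P / P[3, 4]
  c(t(P))[1:11]
}

# Hartley-style similarity normalization of an n x d coordinate matrix;
# returns the (d+1) x (d+1) homogeneous transform and the transformed points
normalize_coords <- function(X) {
  d <- ncol(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  s <- sqrt(d) / mean(row_norm3(Xc))
  Tm <- diag(c(rep(s, d), 1))
  Tm[seq_len(d), d + 1] <- -s * ctr
  list(T = Tm, X = Xc * s)
}

row_norm3 <- function(m) sqrt(rowSums(m * m))

#' Estimate an 11-parameter DLT camera calibration
#'
#' Fits the 11 DLT coefficients of one camera from digitized calibration
#' points (known 3D coordinates plus their 2D pixel coordinates in that
#' camera) by linear least squares on the standard stacked system, two
#' equations per point.  Coordinates are centered and scaled before the
#' solve and the coefficients back-transformed, which stabilizes the
#' conditioning without changing the estimator.
#'
#' @param points a [calibration_points] object (see
#'   [read_calibration_points()]).
#' @param camera_id which camera's pixel observations to use; must match a
#'   name in `points$pixels`.
#' @param refine logical; if `TRUE` the linear solution is polished by a
#'   quasi-Newton minimization of the same stacked-system residual.  The
#'   default `FALSE` is the plain linear DLT.
#' @return an object of class `dlt_calibration` with elements `camera_id`,
#'   `L` (the 11 coefficients), `reprojection_rmse` (pixels, root mean
#'   squared radial reprojection error over the calibration points),
#'   `n_points`, and `df_residual` (`2 * n_points - 11`).
#' @seealso [reproject()], [triangulate()]
#' @export
estimate_dlt <- function(points, camera_id, refine = FALSE) {
  stopifnot(inherits(points, "calibration_points"))
  if (!camera_id %in% names(points$pixels))
    stop_skate("no pixel observations for camera '%s'", camera_id,
               class = "unknown_camera_error")
  X <- as.matrix(points$points[, c("X", "Y", "Z")])
  uv <- points$pixels[[camera_id]]
  keep <- stats::complete.cases(X) & stats::complete.cases(uv)
  X <- X[keep, , drop = FALSE]
  uv <- uv[keep, , drop = FALSE]
  n <- nrow(X)
  if (n < 6)
    stop_skate("DLT needs at least 6 calibration points for camera '%s', got %d",
               camera_id, n, class = "underdetermined_error")

  n3 <- normalize_coords(X)
  n2 <- normalize_coords(uv)
  Xn <- n3$X; uvn <- n2$X

  A <- matrix(0, 2 * n, 11)
  y <- numeric(2 * n)
  odd <- seq(1, 2 * n, by = 2)
  A[odd, 1:3] <- Xn
  A[odd, 4] <- 1
  A[odd, 9:11] <- -uvn[, 1] * Xn
  A[odd + 1, 5:7] <- Xn
  A[odd + 1, 8] <- 1
  A[odd + 1, 9:11] <- -uvn[, 2] * Xn
  y[odd] <- uvn[, 1]
  y[odd + 1] <- uvn[, 2]

  qa <- qr(A)
  if (qa$rank < 11)
    stop_skate(
      "degenerate calibration geometry for camera '%s': design matrix rank %d < 11 (coplanar or collinear points?)",
      camera_id, qa$rank, class = "degenerate_geometry_error")
  Ln <- qr.coef(qa, y)

  if (isTRUE(refine)) {
    obj <- function(l) sum((A %*% l - y)^2)
    gr <- function(l) as.numeric(2 * crossprod(A, A %*% l - y))
    Ln <- optim(Ln, obj, gr, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14))$par
  }

  P <- solve(n2$T) %*% dlt_to_P(Ln) %*% n3$T
  L <- P_to_dlt(P)

  den <- X %*% L[9:11] + 1
  if (any(den <= 0))
    stop_skate(
      "camera '%s' orientation error: projective denominator non-positive at %d calibration point(s)",
      camera_id, sum(den <= 0), class = "orientation_error")

  proj <- dlt_project(L, X)
  res2 <- rowSums((proj - uv)^2)
  structure(list(camera_id = camera_id,
                 L = as.numeric(L),
                 reprojection_rmse = sqrt(mean(res2)),
                 n_points = n,
                 df_residual = 2L * n - 11L,
                 fitted_at = NA_character_),
            class = "dlt_calibration")
}

# vectorized DLT projection of an n x 3 matrix of world points
dlt_project <- function(L, X, tol = 0) {
  X <- as_matrix3(X)
  den <- as.numeric(X %*% L[9:11]) + 1
  if (tol > 0 && any(den <= tol, na.rm = TRUE))
    stop_skate("point behind camera: projective denominator <= %g", tol,
               class = "behind_camera_error")
  u <- (as.numeric(X %*% L[1:3]) + L[4]) / den
  v <- (as.numeric(X %*% L[5:7]) + L[8]) / den
  cbind(u = u, v = v)
}

#' Project a 3D point through a DLT calibration
#'
#' Applies the rational DLT mapping exactly.  Errors if the projective
#' denominator is not positive (point at or behind the camera plane).
#'
#' @param calib a `dlt_calibration` object or an 11-vector of coefficients.
#' @param point3d a length-3 vector or an n x 3 matrix of world coordinates
#'   in meters.
#' @param tol positive tolerance on the projective denominator.
#' @return an n x 2 matrix of pixel coordinates (columns `u`, `v`).
#' @export
reproject <- function(calib, point3d, tol = 1e-12) {
  L <- if (inherits(calib, "dlt_calibration")) calib$L else as.numeric(calib)
  stopifnot(length(L) == 11)
  dlt_project(L, point3d, tol = tol)
}

#' @export
print.dlt_calibration <- function(x, ...) {
  cat(sprintf("DLT calibration for camera '%s'\n", x$camera_id))
  cat(sprintf("  points: %d   residual df: %d\n", x$n_points, x$df_residual))
  cat(sprintf("  reprojection RMSE: %.4g px\n", x$reprojection_rmse))
  cat("  L:", paste(sprintf("%.6g", x$L), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.dlt_calibration <- function(object, ...) object$L

#' Triangulate a 3D point from multi-camera pixel observations
#'
#' Solves the stacked DLT equations (two per camera) for the world point by
#' unweighted linear least squares.  Cameras whose confidence is below
#' `conf_threshold`, or whose pixel coordinates are missing, are dropped;
#' if fewer than two cameras remain the point is returned as missing (`NA`)
#' rather than raising an error, so that sporadic detection failures mark
#' frames instead of aborting a trial.
#'
#' @param obs an n_cameras x 2 matrix of pixel coordinates (u, v), one row
#'   per camera, in the order of `calibs`.
#' @param calibs list of `dlt_calibration` objects (>= 2).
#' @param confidence optional per-camera confidences in `[0, 1]`.
#' @param conf_threshold minimum usable confidence (default 0.6).
#' @param condition_warn condition-number threshold of the 3 x 3 normal
#'   matrix above which a narrow-baseline warning is raised (the default
#'   1e3 corresponds to rays a few degrees apart; a wide two-camera rig
#'   sits around 10).
#' @return list with `xyz` (length-3, meters; `NA` if unusable), `residual`
#'   (RMS pixel misfit across the used cameras) and `n_cameras` used.
#' @export
triangulate <- function(obs, calibs, confidence = NULL, conf_threshold = 0.6,
                        condition_warn = 1e3) {
  obs <- matrix(as.numeric(obs), ncol = 2)
  k <- nrow(obs)
  stopifnot(length(calibs) == k)
  use <- stats::complete.cases(obs)
  if (!is.null(confidence)) use <- use & (confidence >= conf_threshold)
  if (sum(use) < 2)
    return(list(xyz = rep(NA_real_, 3), residual = NA_real_, n_cameras = sum(use)))
  A <- NULL; y <- NULL
  for (c in which(use)) {
    L <- if (inherits(calibs[[c]], "dlt_calibration")) calibs[[c]]$L else calibs[[c]]
    u <- obs[c, 1]; v <- obs[c, 2]
    A <- rbind(A,
               c(L[1] - u * L[9], L[2] - u * L[10], L[3] - u * L[11]),
               c(L[5] - v * L[9], L[6] - v * L[10], L[7] - v * L[11]))
    y <- c(y, u - L[4], v - L[8])
  }
  N <- crossprod(A)
  ev <- eigen(N, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] <= 0 || ev[1] / ev[3] > condition_warn)
    warn_skate("ill-conditioned triangulation geometry (normal-matrix condition %.3g): nearly parallel rays",
               if (ev[3] > 0) ev[1] / ev[3] else Inf,
               class = "conditioning_warning")
  xyz <- as.numeric(solve(N, crossprod(A, y)))
  mis <- vapply(which(use), function(c) {
    L <- if (inherits(calibs[[c]], "dlt_calibration")) calibs[[c]]$L else calibs[[c]]
    sum((dlt_project(L, matrix(xyz, 1)) - obs[c, ])^2)
  }, numeric(1))
  list(xyz = xyz, residual = sqrt(mean(mis) / 2), n_cameras = sum(use))
}

# Vectorized two-pass triangulation of whole trajectories: u, v, conf are
# frames x n_cameras matrices for ONE point.  Accumulates per-frame 3 x 3
# normal equations across cameras and solves them in closed form (adjugate),
# which keeps per-frame cost constant.  Returns frames x 3 xyz plus the RMS
# pixel residual per frame; frames with < 2 usable cameras come back NA.
triangulate_series <- function(u, v, conf, calibs, conf_threshold = 0.6) {
  nf <- nrow(u); k <- ncol(u)
  Ls <- lapply(calibs, function(cc) if (inherits(cc, "dlt_calibration")) cc$L else cc)
  usable <- is.finite(u) & is.finite(v) & (conf >= conf_threshold)
  N11 <- N12 <- N13 <- N22 <- N23 <- N33 <- matrix(0, nf, 1)
  b1 <- b2 <- b3 <- matrix(0, nf, 1)
  rowlist <- vector("list", k)
  for (c in seq_len(k)) {
    L <- Ls[[c]]
    w <- as.numeric(usable[, c])
    uu <- ifelse(usable[, c], u[, c], 0)
    vv <- ifelse(usable[, c], v[, c], 0)
    a1 <- cbind(L[1] - uu * L[9], L[2] - uu * L[10], L[3] - uu * L[11])
    a2 <- cbind(L[5] - vv * L[9], L[6] - vv * L[10], L[7] - vv * L[11])
    y1 <- uu - L[4]; y2 <- vv - L[8]
    N11 <- N11 + w * (a1[, 1]^2 + a2[, 1]^2)
    N12 <- N12 + w * (a1[, 1] * a1[, 2] + a2[, 1] * a2[, 2])
    N13 <- N13 + w * (a1[, 1] * a1[, 3] + a2[, 1] * a2[, 3])
    N22 <- N22 + w * (a1[, 2]^2 + a2[, 2]^2)
    N23 <- N23 + w * (a1[, 2] * a1[, 3] + a2[, 2] * a2[, 3])
    N33 <- N33 + w * (a1[, 3]^2 + a2[, 3]^2)
    b1 <- b1 + w * (a1[, 1] * y1 + a2[, 1] * y2)
    b2 <- b2 + w * (a1[, 2] * y1 + a2[, 2] * y2)
    b3 <- b3 + w * (a1[, 3] * y1 + a2[, 3] * y2)
  }
  det <- N11 * (N22 * N33 - N23^2) - N12 * (N12 * N33 - N23 * N13) +
    N13 * (N12 * N23 - N22 * N13)
  # adjugate solve
  x1 <- ((N22 * N33 - N23^2) * b1 + (N13 * N23 - N12 * N33) * b2 +
           (N12 * N23 - N13 * N22) * b3) / det
  x2 <- ((N13 * N23 - N12 * N33) * b1 + (N11 * N33 - N13^2) * b2 +
           (N12 * N13 - N11 * N23) * b3) / det
  x3 <- ((N12 * N23 - N13 * N22) * b1 + (N12 * N13 - N11 * N23) * b2 +
           (N11 * N22 - N12^2) * b3) / det
  xyz <- cbind(as.numeric(x1), as.numeric(x2), as.numeric(x3))
  ncam <- rowSums(usable)
  bad <- ncam < 2 | !is.finite(as.numeric(det)) | as.numeric(det) <= 0
  xyz[bad, ] <- NA_real_
  # RMS pixel residual over used cameras
  ss <- numeric(nf); cnt <- numeric(nf)
  for (c in seq_len(k)) {
    L <- Ls[[c]]
    proj <- dlt_project(L, xyz)
    d2 <- (proj[, 1] - u[, c])^2 + (proj[, 2] - v[, c])^2
    ok <- usable[, c] & !bad
    ss[ok] <- ss[ok] + d2[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  resid <- ifelse(cnt > 0, sqrt(ss / (2 * pmax(cnt, 1))), NA_real_)
  list(xyz = xyz, residual = resid, n_cameras = ncam)
}

#' Express an ideal pinhole camera as DLT coefficients
#'
#' Builds the 3 x 4 projective matrix of a distortion-free pinhole camera
#' from its position, a look-at target, focal length and principal point,
#' and returns it as an 11-vector of DLT coefficients.  Used by the
#' simulator so that the fitted model class contains the generating camera
#' exactly.
#'
#' @param position,target camera center and look-at point, world meters.
#' @param f_px focal length in pixels (same for u and v).
#' @param principal c(cx, cy) principal point in pixels.
#' @param up world up direction (default +z).
#' @return 11-vector of DLT coefficients.
#' @export
dlt_from_pinhole <- function(position, target, f_px = 900,
                             principal = c(640, 360), up = c(0, 0, 1)) {
  zc <- target - position
  zc <- zc / sqrt(sum(zc^2))
  xc <- c(zc[2] * up[3] - zc[3] * up[2],
          zc[3] * up[1] - zc[1] * up[3],
          zc[1] * up[2] - zc[2] * up[1])
  xc <- xc / sqrt(sum(xc^2))
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  R <- rbind(xc, yc, zc)
  K <- rbind(c(f_px, 0, principal[1]),
             c(0, f_px, principal[2]),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% position)
  P_to_dlt(P)
}

#' Write / read DLT calibrations as JSON
#'
#' @param calibs list of `dlt_calibration` objects (or a single one).
#' @param path output JSON path.
#' @return `read_dlt_json` returns a list of `dlt_calibration` objects.
#' @export
write_dlt_json <- function(calibs, path) {
  if (inherits(calibs, "dlt_calibration")) calibs <- list(calibs)
  payload <- lapply(calibs, function(cc)
    list(camera_id = cc$camera_id, L = cc$L,
         reprojection_rmse = cc$reprojection_rmse,
         n_points = cc$n_points, fitted_at = cc$fitted_at))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_dlt_json
#' @export
read_dlt_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$camera_id)) raw <- list(raw)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(cc) {
    L <- as.numeric(unlist(cc$L))
    stopifnot(length(L) == 11)
    structure(list(camera_id = as.character(cc$camera_id), L = L,
                   reprojection_rmse = as.numeric(cc$reprojection_rmse %||% NA),
                   n_points = as.integer(cc$n_points %||% NA),
                   df_residual = 2L * as.integer(cc$n_points %||% 6L) - 11L,
                   fitted_at = as.character(cc$fitted_at %||% NA)),
              class = "dlt_calibration")
  })
}
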