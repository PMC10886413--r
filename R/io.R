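# File formats.
#
# All unit conversions happen here: in-memory lengths are always meters,
# pixel coordinates are always pixels.  Three formats are handled:
#   * 2D keypoints: DeepLabCut-style CSV (3 header rows scorer/bodyparts/
#     coords) or a plain single-header CSV (frame, <pt>_u, <pt>_v, <pt>_conf)
#   * 3D markers: TRC (tab-separated, PathFileType/DataRate header)
#   * calibration points: CSV (label, X, Y, Z, <cam>_u, <cam>_v, ...) or JSON
# Writers use fixed-precision formatting so identical inputs give
# byte-identical files.

new_trajectory2d <- function(camera_id, rate, points, u, v, confidence,
                             width = 1280, height = 720, validate = TRUE) {
  u <- as.matrix(u); v <- as.matrix(v); confidence <- as.matrix(confidence)
  colnames(u) <- colnames(v) <- colnames(confidence) <- points
  obj <- structure(list(camera_id = camera_id, rate = rate, points = points,
                        u = u, v = v, confidence = confidence,
                        width = width, height = height),
                   class = "trajectory2d")
  if (validate) validate_trajectory2d(obj)
  obj
}

validate_trajectory2d <- function(x) {
  if (anyDuplicated(x$points))
    stop_skate("duplicate point labels: %s",
               paste(unique(x$points[duplicated(x$points)]), collapse = ", "),
               class = "format_error")
  bad_u <- which(is.finite(x$u) & (x$u < 0 | x$u >= x$width), arr.ind = TRUE)
  bad_v <- which(is.finite(x$v) & (x$v < 0 | x$v >= x$height), arr.ind = TRUE)
  bad <- rbind(bad_u, bad_v)
  if (nrow(bad) > 0)
    stop_skate("pixel coordinate out of bounds at frame %d, point '%s'",
               bad[1, 1], x$points[bad[1, 2]], class = "bounds_error")
  if (any(is.finite(x$confidence) & (x$confidence < 0 | x$confidence > 1)))
    stop_skate("confidence values outside [0, 1]", class = "bounds_error")
  invisible(x)
}

#' @export
print.trajectory2d <- function(x, ...) {
  cat(sprintf("2D keypoint trajectory, camera '%s': %d frames x %d points @ %g Hz (%d x %d px)\n",
              x$camera_id, nrow(x$u), length(x$points), x$rate, x$width, x$height))
  cat("  points:", paste(x$points, collapse = ", "), "\n")
  invisible(x)
}

#' Read 2D keypoint trajectories
#'
#' Reads per-camera pixel keypoint time series with confidences.  The
#' DeepLabCut dialect (three header rows: scorer, bodyparts, coords) and a
#' plain single-header CSV (`frame, <pt>_u, <pt>_v, <pt>_conf`) are both
#' accepted; `dialect = "auto"` sniffs the first cell.  Missing cells become
#' confidence 0 with `NA` coordinates.
#'
#' @param path CSV file path.
#' @param dialect one of `"auto"`, `"dlc-csv"`, `"plain-csv"`.
#' @param rate sampling rate in Hz (not stored in either dialect).
#' @param camera_id camera label; default the file name without extension.
#' @param width,height declared sensor resolution used for bounds checks.
#' @return a `trajectory2d` object.
#' @export
read_keypoints_2d <- function(path, dialect = c("auto", "dlc-csv", "plain-csv"),
                              rate = 100, camera_id = NULL,
                              width = 1280, height = 720) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_skate("keypoint file not found: %s", path, class = "io_error")
  camera_id <- camera_id %||% sub("\\.[^.]*$", "", basename(path))
  first <- strsplit(readLines(path, n = 1), ",")[[1]][1]
  if (dialect == "auto")
    dialect <- if (identical(tolower(first), "scorer")) "dlc-csv" else "plain-csv"

  if (dialect == "dlc-csv") {
    hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                           colClasses = "character")
    if (!identical(tolower(hdr[1, 1]), "scorer") ||
        !identical(tolower(hdr[2, 1]), "bodyparts") ||
        !identical(tolower(hdr[3, 1]), "coords"))
      stop_skate("malformed DeepLabCut header in %s: expected scorer/bodyparts/coords rows",
                 path, class = "format_error")
    coords <- tolower(as.character(hdr[3, -1]))
    parts <- as.character(hdr[2, -1])
    if (length(coords) %% 3 != 0 ||
        !all(coords == rep(c("x", "y", "likelihood"), length(coords) / 3)))
      stop_skate("malformed DeepLabCut header in %s: coords row must repeat x,y,likelihood (offending column %d)",
                 path, which(coords != rep(c("x", "y", "likelihood"),
                                           length.out = length(coords)))[1] + 1,
                 class = "format_error")
    pts <- parts[seq(1, length(parts), by = 3)]
    dat <- utils::read.csv(path, header = FALSE, skip = 3)
    frames <- dat[, 1]
    m <- as.matrix(dat[, -1, drop = FALSE])
    u <- m[, seq(1, ncol(m), by = 3), drop = FALSE]
    v <- m[, seq(2, ncol(m), by = 3), drop = FALSE]
    conf <- m[, seq(3, ncol(m), by = 3), drop = FALSE]
  } else {
    dat <- utils::read.csv(path, header = TRUE, check.names = FALSE)
    cn <- names(dat)
    if (cn[1] != "frame")
      stop_skate("malformed header in %s: first column must be 'frame', got '%s'",
                 path, cn[1], class = "format_error")
    rest <- cn[-1]
    if (length(rest) %% 3 != 0)
      stop_skate("malformed header in %s: keypoint columns must come in _u/_v/_conf triples",
                 path, class = "format_error")
    pts <- sub("_u$", "", rest[seq(1, length(rest), by = 3)])
    expect <- as.vector(rbind(paste0(pts, "_u"), paste0(pts, "_v"),
                              paste0(pts, "_conf")))
    if (!identical(rest, expect)) {
      off <- which(rest != expect)[1]
      stop_skate("malformed header in %s: column '%s' (expected '%s')",
                 path, rest[off], expect[off], class = "format_error")
    }
    frames <- dat[[1]]
    m <- as.matrix(dat[, -1, drop = FALSE])
    u <- m[, seq(1, ncol(m), by = 3), drop = FALSE]
    v <- m[, seq(2, ncol(m), by = 3), drop = FALSE]
    conf <- m[, seq(3, ncol(m), by = 3), drop = FALSE]
  }

  if (any(diff(frames) <= 0))
    stop_skate("non-monotone frame index in %s at row %d", path,
               which(diff(frames) <= 0)[1] + 1, class = "sequencing_error")
  missing <- !is.finite(u) | !is.finite(v)
  conf[missing] <- 0
  u[missing] <- NA_real_
  v[missing] <- NA_real_
  new_trajectory2d(camera_id, rate, pts, u, v, conf, width, height)
}

#' Write 2D keypoint trajectories
#'
#' The canonical dialect is the DeepLabCut 3-row-header CSV; coordinates are
#' written with 6 decimals so `write(read(f))` is byte-identical for files
#' produced by this writer.
#'
#' @param traj a `trajectory2d` object.
#' @param path output path.
#' @param dialect `"dlc-csv"` (canonical) or `"plain-csv"`.
#' @param scorer scorer label written in the DeepLabCut header row.
#' @export
write_keypoints_2d <- function(traj, path, dialect = c("dlc-csv", "plain-csv"),
                               scorer = "skate3d") {
  dialect <- match.arg(dialect)
  stopifnot(inherits(traj, "trajectory2d"))
  nf <- nrow(traj$u)
  np <- length(traj$points)
  cells <- matrix("", nf, 3 * np)
  cells[, seq(1, 3 * np, by = 3)] <- fmt_num(traj$u)
  cells[, seq(2, 3 * np, by = 3)] <- fmt_num(traj$v)
  cells[, seq(3, 3 * np, by = 3)] <- fmt_num(traj$confidence)
  body <- paste(seq_len(nf) - 1L, apply(cells, 1, paste, collapse = ","),
                sep = ",")
  if (dialect == "dlc-csv") {
    h1 <- paste(c("scorer", rep(scorer, 3 * np)), collapse = ",")
    h2 <- paste(c("bodyparts", rep(traj$points, each = 3)), collapse = ",")
    h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), np)), collapse = ",")
    lines <- c(h1, h2, h3, body)
  } else {
    h <- paste(c("frame", as.vector(rbind(paste0(traj$points, "_u"),
                                          paste0(traj$points, "_v"),
                                          paste0(traj$points, "_conf")))),
               collapse = ",")
    lines <- c(h, body)
  }
  writeLines(lines, path)
  invisible(path)
}

new_markerset3d <- function(rate, data, gap_mask = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 3)
  if (is.null(gap_mask))
    gap_mask <- apply(data, c(1, 2), function(z) any(!is.finite(z)))
  structure(list(rate = rate, markers = dimnames(data)[[2]],
                 data = data, gap_mask = gap_mask),
            class = "markerset3d")
}

#' @export
print.markerset3d <- function(x, ...) {
  cat(sprintf("3D marker set: %d frames x %d markers @ %g Hz (%d gap cells)\n",
              dim(x$data)[1], dim(x$data)[2], x$rate, sum(x$gap_mask)))
  invisible(x)
}

# pull one marker as frames x 3
marker_xyz <- function(ms, label) {
  if (!label %in% ms$markers)
    stop_skate("marker-set incomplete: missing marker '%s'", label,
               class = "marker_missing_error")
  ms$data[, label, , drop = TRUE]
}

#' Read a TRC marker trajectory file
#'
#' Reads the tab-separated TRC format (header rows `PathFileType`, the
#' DataRate line, and the marker-name / XYZ column rows).  Coordinates are
#' converted to meters when the header declares `mm`; empty cells are
#' treated as gaps and masked.
#'
#' @param path TRC file path.
#' @param required_markers optional character vector; an error listing the
#'   absent labels is raised if any are missing.
#' @return a `markerset3d` object: `rate`, `markers`, a frames x markers x 3
#'   coordinate array in meters, and a logical `gap_mask`.
#' @export
read_markers_trc <- function(path, required_markers = NULL) {
  if (!file.exists(path))
    stop_skate("TRC file not found: %s", path, class = "io_error")
  lines <- readLines(path)
  if (!startsWith(lines[1], "PathFileType"))
    stop_skate("malformed TRC header in %s: first line must start with PathFileType",
               path, class = "format_error")
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  meta <- stats::setNames(as.list(vals), keys)
  if (is.null(meta$DataRate))
    stop_skate("malformed TRC header in %s: no DataRate field", path,
               class = "format_error")
  rate <- as.numeric(meta$DataRate)
  units <- meta$Units %||% "m"
  scale <- if (tolower(units) == "mm") 1e-3 else 1
  labels_row <- strsplit(lines[4], "\t")[[1]]
  markers <- labels_row[-(1:2)]
  markers <- markers[markers != ""]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[trimws(data_lines) != ""]
  nf <- length(data_lines)
  nm <- length(markers)
  arr <- array(NA_real_, c(nf, nm, 3),
               dimnames = list(NULL, markers, c("x", "y", "z")))
  for (i in seq_len(nf)) {
    cells <- strsplit(data_lines[i], "\t")[[1]]
    need <- 2 + 3 * nm
    if (length(cells) < need) cells <- c(cells, rep("", need - length(cells)))
    xyz <- suppressWarnings(as.numeric(cells[3:need]))
    arr[i, , ] <- matrix(xyz, nm, 3, byrow = TRUE)
  }
  arr <- arr * scale
  if (!is.null(required_markers)) {
    absent <- setdiff(required_markers, markers)
    if (length(absent) > 0)
      stop_skate("marker-set incomplete: missing markers %s",
                 paste(absent, collapse = ", "), class = "marker_missing_error")
  }
  new_markerset3d(rate, arr)
}

#' Write a TRC marker trajectory file
#'
#' @param ms a `markerset3d` object (coordinates in meters).
#' @param path output path.
#' @param units `"m"` or `"mm"` for the written coordinates.
#' @export
write_markers_trc <- function(ms, path, units = "m") {
  stopifnot(inherits(ms, "markerset3d"))
  scale <- if (units == "mm") 1e3 else 1
  nf <- dim(ms$data)[1]; nm <- dim(ms$data)[2]
  h1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  h2 <- paste(c("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames"),
              collapse = "\t")
  h3 <- paste(c(fmt_num(ms$rate, 2), fmt_num(ms$rate, 2), nf, nm, units,
                fmt_num(ms$rate, 2), 1, nf), collapse = "\t")
  h4 <- paste(c("Frame#", "Time",
                as.vector(rbind(ms$markers, "", ""))), collapse = "\t")
  h5 <- paste(c("", "", as.vector(rbind(paste0("X", seq_len(nm)),
                                        paste0("Y", seq_len(nm)),
                                        paste0("Z", seq_len(nm))))),
              collapse = "\t")
  t <- (seq_len(nf) - 1L) / ms$rate
  body <- vapply(seq_len(nf), function(i) {
    xyz <- t(ms$data[i, , , drop = TRUE] * scale)  # 3 x nm
    paste(c(i, fmt_num(t[i]), fmt_num(as.vector(xyz))), collapse = "\t")
  }, character(1))
  writeLines(c(h1, h2, h3, h4, h5, "", body), path)
  invisible(path)
}

#' Calibration point sets
#'
#' A calibration point set holds labeled 3D coordinates (meters) together
#' with their manually digitized pixel coordinates in each camera.  At
#' least 6 points per camera are required for the 11-parameter DLT; a
#' near-coplanar 3D configuration triggers a warning because it makes the
#' calibration ill-conditioned.
#'
#' @param points data.frame with columns `label`, `X`, `Y`, `Z` (meters).
#' @param pixels named list, one n x 2 (u, v) matrix per camera.
#' @return an object of class `calibration_points`.
#' @export
calibration_points <- function(points, pixels) {
  stopifnot(is.data.frame(points),
            all(c("label", "X", "Y", "Z") %in% names(points)))
  pixels <- lapply(pixels, function(m) {
    m <- matrix(as.numeric(as.matrix(m)), ncol = 2)
    colnames(m) <- c("u", "v")
    m
  })
  for (cam in names(pixels)) {
    n_ok <- sum(stats::complete.cases(pixels[[cam]]))
    if (n_ok < 6)
      stop_skate("camera '%s' has only %d digitized points; DLT needs >= 6 (11 unknowns)",
                 cam, n_ok, class = "underdetermined_error")
  }
  X <- as.matrix(points[, c("X", "Y", "Z")])
  sv <- svd(sweep(X, 2, colMeans(X)))$d
  if (sv[3] < 1e-3 * sv[1])
    warn_skate("calibration points are (near-)coplanar: smallest/largest singular value ratio %.3g; DLT will be ill-conditioned",
               sv[3] / sv[1], class = "coplanar_warning")
  structure(list(points = points, pixels = pixels), class = "calibration_points")
}

#' @export
print.calibration_points <- function(x, ...) {
  cat(sprintf("Calibration point set: %d points, cameras: %s\n",
              nrow(x$points), paste(names(x$pixels), collapse = ", ")))
  invisible(x)
}

#' Read / write calibration points
#'
#' CSV schema: `label, X, Y, Z, <cam>_u, <cam>_v, ...` with one `_u`/`_v`
#' column pair per camera; JSON mirrors the in-memory structure.  The
#' format is chosen by file extension.
#'
#' @param path file path (`.csv` or `.json`).
#' @return a `calibration_points` object.
#' @export
read_calibration_points <- function(path) {
  if (!file.exists(path))
    stop_skate("calibration point file not found: %s", path, class = "io_error")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- as.data.frame(raw$points)
    pix <- lapply(raw$pixels, function(m) matrix(as.numeric(as.matrix(m)), ncol = 2))
    return(calibration_points(pts, pix))
  }
  dat <- utils::read.csv(path, check.names = FALSE)
  need <- c("label", "X", "Y", "Z")
  if (!all(need %in% names(dat)))
    stop_skate("calibration CSV %s must have columns label, X, Y, Z", path,
               class = "format_error")
  rest <- setdiff(names(dat), need)
  ucols <- grep("_u$", rest, value = TRUE)
  cams <- sub("_u$", "", ucols)
  if (length(cams) == 0 || !all(paste0(cams, "_v") %in% rest))
    stop_skate("calibration CSV %s needs <camera>_u and <camera>_v column pairs",
               path, class = "format_error")
  pixels <- lapply(cams, function(cam)
    cbind(u = dat[[paste0(cam, "_u")]], v = dat[[paste0(cam, "_v")]]))
  names(pixels) <- cams
  calibration_points(dat[, need], pixels)
}

#' @rdname read_calibration_points
#' @param cps a `calibration_points` object.
#' @export
write_calibration_points <- function(cps, path) {
  stopifnot(inherits(cps, "calibration_points"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(points = cps$points, pixels = cps$pixels),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  df <- cps$points[, c("label", "X", "Y", "Z")]
  out <- data.frame(label = df$label, X = fmt_num(df$X), Y = fmt_num(df$Y),
                    Z = fmt_num(df$Z), check.names = FALSE)
  for (cam in names(cps$pixels)) {
    out[[paste0(cam, "_u")]] <- fmt_num(cps$pixels[[cam]][, 1])
    out[[paste0(cam, "_v")]] <- fmt_num(cps$pixels[[cam]][, 2])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_trajectory3d <- function(rate, data, residual = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == 3)
  structure(list(rate = rate, points = dimnames(data)[[2]],
                 data = data, residual = residual),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  nmiss <- sum(!is.finite(x$data[, , 1]))
  cat(sprintf("3D trajectory: %d frames x %d points @ %g Hz (%d missing point-frames)\n",
              dim(x$data)[1], length(x$points), x$rate, nmiss))
  if (!is.null(x$residual))
    cat(sprintf("  median reconstruction residual: %.3g px\n",
                stats::median(x$residual, na.rm = TRUE)))
  invisible(x)
}

point_xyz <- function(traj, label) {
  if (!label %in% traj$points)
    stop_skate("trajectory has no point '%s'", label, class = "label_error")
  traj$data[, label, , drop = TRUE]
}
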