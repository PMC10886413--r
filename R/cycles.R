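# Cycle segmentation and time normalization.
#
# A skiing cycle starts at a right-pole treadmill contact.  With the G1
# technique there is one pole impact per cycle, so consecutive strikes
# delimit cycles; with G3 there are two impacts per cycle, so every second
# strike is a cycle boundary.  Each cycle is resampled to a fixed number of
# normalized time samples (101 by default, 0-100% inclusive) by linear
# interpolation, and the first `n_cycles` complete cycles are selected.

cycle_boundaries <- function(strikes, technique) {
  s <- as.integer(strikes)
  if (technique == "G3") s <- s[seq(1, length(s), by = 2)]
  s
}

#' Segment and time-normalize skiing cycles
#'
#' @param x signal to segment: a `trajectory3d` or `joint_centers` (points),
#'   an `angle_series` or plain matrix (channels in columns), or a vector.
#' @param strikes right-pole strike frames ([detect_pole_strikes()]).
#' @param technique `"G1"` (every strike a boundary) or `"G3"` (every
#'   second strike).
#' @param n_cycles number of cycles to keep (default 10).
#' @param n_samples normalized samples per cycle, 0-100% inclusive
#'   (default 101).
#' @return a `cycle_set`: for point input `values` is a cycles x samples x
#'   points x 3 array, otherwise cycles x samples x channels; plus
#'   `technique`, `boundaries` (frame indices used) and `n_samples`.
#' @export
segment_cycles <- function(x, strikes, technique = c("G1", "G3"),
                           n_cycles = 10, n_samples = 101) {
  technique <- match.arg(technique)
  bounds <- cycle_boundaries(strikes, technique)
  avail <- length(bounds) - 1L
  if (avail < n_cycles)
    stop_skate("insufficient cycles: %d complete cycles available, %d requested",
               max(avail, 0L), n_cycles, class = "insufficient_cycles_error")
  bounds <- bounds[seq_len(n_cycles + 1L)]

  resample1 <- function(v, from, to) {
    idx <- seq(from, to, length.out = n_samples)
    approx(x = seq_along(v), y = v, xout = idx, rule = 2)$y
  }

  if (inherits(x, c("trajectory3d", "joint_centers"))) {
    arr <- x$data
    pts <- dimnames(arr)[[2]]
    vals <- array(NA_real_, c(n_cycles, n_samples, length(pts), 3),
                  dimnames = list(NULL, NULL, pts, c("x", "y", "z")))
    for (ci in seq_len(n_cycles))
      for (p in seq_along(pts))
        for (d in 1:3)
          vals[ci, , p, d] <- resample1(arr[, p, d], bounds[ci], bounds[ci + 1])
    kind <- "points"
    items <- pts
  } else {
    m <- if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1) else unclass(x)
    items <- colnames(m) %||% paste0("ch", seq_len(ncol(m)))
    vals <- array(NA_real_, c(n_cycles, n_samples, ncol(m)),
                  dimnames = list(NULL, NULL, items))
    for (ci in seq_len(n_cycles))
      for (j in seq_len(ncol(m)))
        vals[ci, , j] <- resample1(m[, j], bounds[ci], bounds[ci + 1])
    kind <- "channels"
  }
  structure(list(technique = technique, kind = kind, items = items,
                 values = vals, n_cycles = n_cycles, n_samples = n_samples,
                 boundaries = bounds),
            class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  cat(sprintf("Cycle set (%s, %s): %d cycles x %d samples, items: %s\n",
              x$technique, x$kind, x$n_cycles, x$n_samples,
              paste(x$items, collapse = ", ")))
  invisible(x)
}

#' Per-sample Euclidean distances between two point cycle sets
#'
#' Computes the 3D Euclidean distance between matching points of two cycle
#' sets at every cycle and normalized time sample.  This is the
#' joint-center comparison statistic: distances are magnitudes, so they are
#' strictly non-negative and their mean is not a signed bias.
#'
#' @param a,b `cycle_set` objects of kind `points` with identical
#'   technique, cycle count, sample count and point labels.
#' @return cycles x samples x points array of distances in meters.
#' @export
euclidean_distance_series <- function(a, b) {
  stopifnot(inherits(a, "cycle_set"), inherits(b, "cycle_set"))
  if (a$kind != "points" || b$kind != "points")
    stop_skate("euclidean distances need point cycle sets", class = "label_error")
  if (!identical(a$items, b$items))
    stop_skate("point labels differ between cycle sets: %s vs %s",
               paste(a$items, collapse = ","), paste(b$items, collapse = ","),
               class = "label_error")
  if (a$n_cycles != b$n_cycles || a$n_samples != b$n_samples)
    stop_skate("cycle set shapes differ", class = "label_error")
  d <- sqrt(apply((a$values - b$values)^2, c(1, 2, 3), sum))
  dimnames(d) <- dimnames(a$values)[1:3]
  d
}
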