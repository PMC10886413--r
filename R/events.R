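# Pole-strike event detection and system synchronization.
#
# Trials start when the skier strikes the treadmill with the right pole, and
# skiing cycles are delimited by successive right-pole contacts.  A strike
# is detected as the first frame of a downward crossing of the pole-tip
# vertical coordinate below a contact band (5th percentile of the series
# plus 10 mm by default), with a refractory period so bounce or filter
# ringing near contact cannot double-count an impact.

#' Detect pole-strike events from a pole-tip height series
#'
#' @param z vertical coordinate of the pole tip (meters), uniformly sampled.
#' @param rate sampling rate in Hz.
#' @param threshold contact threshold in meters; default
#'   `quantile(z, 0.05) + 0.010`.
#' @param refractory minimum time between successive strikes in seconds
#'   (default 0.3).
#' @return an integer vector of strike frame indices (class `pole_strikes`)
#'   with the threshold and rate attached as attributes.
#' @export
detect_pole_strikes <- function(z, rate, threshold = NULL, refractory = 0.3) {
  z <- as.numeric(z)
  ok <- is.finite(z)
  if (!all(ok)) z[!ok] <- Inf  # missing frames can never be contacts
  if (is.null(threshold))
    threshold <- as.numeric(quantile(z[ok], 0.05, names = FALSE)) + 0.010
  below <- z < threshold
  n <- length(z)
  cross <- which(!below[-n] & below[-1]) + 1L
  if (length(cross) == 0)
    stop_skate("no pole-strike events: series never crosses the contact threshold %.4g m",
               threshold, class = "no_event_error")
  gap <- max(1L, as.integer(round(refractory * rate)))
  keep <- cross[1]
  for (f in cross[-1]) if (f - keep[length(keep)] >= gap) keep <- c(keep, f)
  structure(keep, class = "pole_strikes", threshold = threshold, rate = rate)
}

#' @export
print.pole_strikes <- function(x, ...) {
  cat(sprintf("%d pole strikes (threshold %.4g m): frames %s%s\n",
              length(x), attr(x, "threshold"),
              paste(utils::head(unclass(x), 8), collapse = ", "),
              if (length(x) > 8) ", ..." else ""))
  invisible(x)
}

#' Synchronize two recordings on their first pole strike
#'
#' Aligns two uniformly sampled sources (e.g. the markerless video chain
#' and the marker-based system) by integer-frame shift so that their first
#' detected pole strikes coincide, then trims both to the overlapping span.
#' Sub-frame alignment is not attempted: both systems run at 100 Hz and
#' events are defined on frames.
#'
#' @param traj_a,traj_b numeric vectors or matrices (frames in rows).
#' @param events_a,events_b `pole_strikes` (or integer vectors) for each
#'   source, on the frame axes of `traj_a` / `traj_b`.
#' @return list with `lag` (frames by which `b` trails `a`), the trimmed
#'   `a` and `b` (equal number of frames), and the strike events re-indexed
#'   to the common (trimmed) frame axis as `events`.
#' @export
synchronize <- function(traj_a, traj_b, events_a, events_b) {
  fa <- as.integer(events_a)[1]
  fb <- as.integer(events_b)[1]
  if (is.na(fa) || is.na(fb))
    stop_skate("both sources need at least one detected pole strike",
               class = "no_event_error")
  lag <- fb - fa
  nA <- if (is.matrix(traj_a)) nrow(traj_a) else length(traj_a)
  nB <- if (is.matrix(traj_b)) nrow(traj_b) else length(traj_b)
  # frame i of a corresponds to frame i + lag of b
  startA <- max(1L, 1L - lag)
  endA <- min(nA, nB - lag)
  idxA <- startA:endA
  idxB <- idxA + lag
  slice <- function(x, idx) if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
  ea <- as.integer(events_a) - startA + 1L
  eb <- as.integer(events_b) - lag - startA + 1L
  ea <- ea[ea >= 1 & ea <= length(idxA)]
  eb <- eb[eb >= 1 & eb <= length(idxA)]
  if (length(ea) != length(eb))
    warn_skate("synchronization quality: %d vs %d strikes in the common span",
               length(ea), length(eb), class = "sync_warning")
  list(lag = lag, a = slice(traj_a, idxA), b = slice(traj_b, idxB),
       events = ea, events_a = ea, events_b = eb,
       frames_a = idxA, frames_b = idxB)
}
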