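# Low-pass Butterworth filtering.
#
# Kinematic time series are smoothed with a 4th-order low-pass Butterworth
# filter applied in a zero-phase (forward-backward) fashion: pixel
# trajectories at a 12 Hz cutoff before triangulation and 3D trajectories at
# 6 Hz afterwards.  The dual pass squares the magnitude response (about 0.5
# instead of the single-pass 1/sqrt(2) at the cutoff) but cancels the phase
# response, which matters because downstream cycle events are defined on the
# filtered signals.

butter_coeffs <- function(cutoff, rate, order = 4) {
  if (rate <= 2 * cutoff)
    stop_skate("sampling rate (%g Hz) must exceed twice the cutoff (%g Hz)",
               rate, cutoff, class = "filter_rate_error")
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# steady-state initial conditions for the direct-form-II-transposed filter,
# scaled by the first input sample before use (suppresses start-up transients)
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  # companion-matrix formulation: solve (I - A^T) zi = B
  A <- matrix(0, n, n)
  A[1, ] <- -a[-1] / a[1]
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(A), B)
}

# causal IIR filter, direct form II transposed, with explicit initial state
lfilter <- function(b, a, x, zi = NULL) {
  n <- length(a) - 1L
  z <- if (is.null(zi)) numeric(n) else as.numeric(zi)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 1) {
      for (k in 1:(n - 1)) z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
    }
    z[n] <- b[n + 1] * xi - a[n + 1] * yi
    y[i] <- yi
  }
  y
}

filtfilt_refl <- function(b, a, x, padlen = NULL, clip_pad = FALSE) {
  if (is.null(padlen)) padlen <- 3L * max(length(a), length(b))
  if (clip_pad) padlen <- min(padlen, length(x) - 1L)
  n <- length(x)
  if (n <= padlen)
    stop_skate(
      "series of length %d is too short to filter: at least %d samples required",
      n, padlen + 1L, class = "filter_length_error")
  # odd (point-reflected) extension at both ends
  front <- 2 * x[1] - x[(padlen + 1L):2L]
  back  <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(front, x, back)
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

#' Low-pass Butterworth filter for kinematic time series
#'
#' Applies a low-pass Butterworth filter to a uniformly sampled series.  The
#' default is the biomechanics convention: a 4th-order filter run forward and
#' backward (zero phase), with odd-reflection padding at the ends to suppress
#' edge transients.  Columns of a matrix input are filtered independently;
#' non-finite runs are not handled and must be dealt with upstream.
#'
#' @param x numeric vector or matrix (one series per column).
#' @param cutoff cutoff frequency in Hz.  The single-pass magnitude response
#'   is -3 dB at `cutoff`; the default dual pass gives about -6 dB there.
#' @param rate sampling rate in Hz; must exceed `2 * cutoff`.
#' @param order filter order (default 4).
#' @param zero_phase logical; `TRUE` (default) runs the filter forward and
#'   backward, `FALSE` gives a single causal pass.
#' @param padlen reflection padding length in samples; the default scales
#'   with the filter time constant (`8 * rate / cutoff`, at least 15) so
#'   start-up transients decay inside the pad.  The series must be longer
#'   than `padlen`.
#' @return filtered series with the shape of `x`.
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' x <- sin(2 * pi * 1 * t) + sin(2 * pi * 30 * t)
#' y <- filter_lowpass(x, cutoff = 6, rate = 100)
#' @export
filter_lowpass <- function(x, cutoff, rate, order = 4, zero_phase = TRUE,
                           padlen = NULL) {
  co <- butter_coeffs(cutoff, rate, order)
  clip_pad <- is.null(padlen)
  if (clip_pad) padlen <- max(15L, as.integer(ceiling(8 * rate / cutoff)))
  apply1 <- function(v) {
    if (zero_phase) {
      if (clip_pad && length(v) <= 15L)
        stop_skate(
          "series of length %d is too short to filter: at least %d samples required",
          length(v), 16L, class = "filter_length_error")
      filtfilt_refl(co$b, co$a, v, padlen = padlen, clip_pad = clip_pad)
    } else {
      zi <- lfilter_zi(co$b, co$a)
      lfilter(co$b, co$a, v, zi * v[1])
    }
  }
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- apply1(x[, j])
    out
  } else {
    apply1(as.numeric(x))
  }
}
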