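# Shared fixtures: a known pinhole camera pair and the 2 m calibration cube.

cube_corners <- function() {
  m <- as.matrix(expand.grid(X = c(0, 2), Y = c(0, 2), Z = c(0, 2)))
  dimnames(m) <- list(NULL, c("X", "Y", "Z"))
  m
}

test_cameras <- function() {
  list(cam0 = dlt_from_pinhole(c(4.70, 1.75, 1.05), c(1.5, 1.75, 1.0),
                               f_px = 700, principal = c(640, 360)),
       cam1 = dlt_from_pinhole(c(4.04, 0.41, 2.50), c(1.5, 1.75, 1.0),
                               f_px = 550, principal = c(640, 360)))
}

# calibration point set: cube corners digitized exactly (plus optional pixel
# noise) through the test cameras
cube_calibration_points <- function(noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  corners <- cube_corners()
  cams <- test_cameras()
  pix <- lapply(cams, function(L) {
    uv <- reproject(L, corners)
    if (noise_sd > 0) uv <- uv + matrix(rnorm(length(uv), 0, noise_sd), ncol = 2)
    uv
  })
  calibration_points(
    data.frame(label = paste0("c", 1:8), X = corners[, 1], Y = corners[, 2],
               Z = corners[, 3]),
    pix)
}

# amplitude and phase of a sinusoid at frequency f in a series (LS fit on a
# trimmed central window)
fit_sinusoid <- function(x, f, rate, trim = 100) {
  n <- length(x)
  idx <- (trim + 1):(n - trim)
  t <- (idx - 1) / rate
  X <- cbind(1, sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- qr.solve(X, x[idx])
  list(amplitude = sqrt(cf[2]^2 + cf[3]^2), phase = atan2(cf[3], cf[2]))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

`%||%` <- function(a, b) if (is.null(a)) b else a
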