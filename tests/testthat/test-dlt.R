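test_that("noise-free cube calibration reproduces the generating camera", {
  cps <- cube_calibration_points()
  cams <- test_cameras()
  for (cam in names(cams)) {
    fit <- estimate_dlt(cps, cam)
    expect_lt(fit$reprojection_rmse, 1e-9)
    # reprojections over a 3D test grid match the true pinhole mapping
    grid <- as.matrix(expand.grid(seq(0.2, 1.8, length.out = 5),
                                  seq(0.2, 1.8, length.out = 5),
                                  seq(0.1, 1.7, length.out = 5)))
    err <- abs(reproject(fit, grid) - reproject(cams[[cam]], grid))
    expect_lt(max(err), 1e-8)
  }
})

test_that("six points give a unique solution with one residual dof", {
  cps <- cube_calibration_points()
  sub <- calibration_points(cps$points[1:6, ],
                            lapply(cps$pixels, function(m) m[1:6, ]))
  fit <- estimate_dlt(sub, "cam0")
  expect_equal(fit$df_residual, 1L)   # 12 equations, 11 unknowns
  expect_lt(fit$reprojection_rmse, 1e-9)
  five <- cps$points[1:5, ]
  expect_error(calibration_points(five, lapply(cps$pixels, function(m) m[1:5, ])),
               class = "underdetermined_error")
})

test_that("linear solve agrees with an independent optimizer on the stacked system", {
  cps <- cube_calibration_points(noise_sd = 1, seed = 11)
  fit <- estimate_dlt(cps, "cam0")
  # independent route: replicate the estimator's definition (center/scale
  # both coordinate sets, stack two equations per point) but solve it with
  # a BFGS optimizer from a perturbed start instead of a linear solve
  X <- as.matrix(cps$points[, c("X", "Y", "Z")])
  uv <- cps$pixels$cam0
  norm1 <- function(M) {
    ctr <- colMeans(M)
    Mc <- sweep(M, 2, ctr)
    s <- sqrt(ncol(M)) / mean(sqrt(rowSums(Mc^2)))
    Tm <- diag(c(rep(s, ncol(M)), 1)); Tm[seq_len(ncol(M)), ncol(M) + 1] <- -s * ctr
    list(T = Tm, M = Mc * s)
  }
  n3 <- norm1(X); n2 <- norm1(uv)
  Xn <- n3$M; uvn <- n2$M
  A <- matrix(0, 16, 11); y <- numeric(16)
  for (i in 1:8) {
    A[2 * i - 1, ] <- c(Xn[i, ], 1, rep(0, 4), -uvn[i, 1] * Xn[i, ])
    A[2 * i, ] <- c(rep(0, 4), Xn[i, ], 1, -uvn[i, 2] * Xn[i, ])
    y[2 * i - 1] <- uvn[i, 1]; y[2 * i] <- uvn[i, 2]
  }
  set.seed(1)
  start <- rep(0.1, 11)
  Ln <- optim(start, function(l) sum((A %*% l - y)^2),
              function(l) as.numeric(2 * crossprod(A, A %*% l - y)),
              method = "BFGS",
              control = list(maxit = 10000, reltol = 1e-16))$par
  Pn <- rbind(Ln[1:4], Ln[5:8], c(Ln[9:11], 1))
  P <- solve(n2$T) %*% Pn %*% n3$T
  ref <- (c(t(P)) / P[3, 4])[1:11]
  expect_lt(max(abs(fit$L - ref) / pmax(abs(fit$L), 1e-8)), 1e-6)
})

test_that("reprojection follows the closed-form DLT mapping", {
  L <- test_cameras()$cam0
  # origin maps to (L4, L8)
  expect_equal(as.numeric(reproject(L, c(0, 0, 0))), c(L[4], L[8]),
               tolerance = 1e-12)
  # independent 3x4 projective-matrix oracle on random points
  set.seed(42)
  P <- rbind(L[1:4], L[5:8], c(L[9:11], 1))
  pts <- cbind(runif(50, 0, 2.5), runif(50, 0, 3), runif(50, 0, 2))
  got <- reproject(L, pts)
  hom <- P %*% rbind(t(pts), 1)
  expect_lt(max(abs(got - t(hom[1:2, ] / rep(hom[3, ], each = 2)))), 1e-10)
  # points at/behind the camera plane error out
  behind <- c(8, 1.75, 1)  # beyond the camera, denominator flips sign
  expect_error(reproject(L, behind), class = "behind_camera_error")
})

test_that("calibration is equivariant under scaling of the 3D frame", {
  cps <- cube_calibration_points(noise_sd = 0.5, seed = 3)
  fit <- estimate_dlt(cps, "cam1")
  s <- 3.7
  scaled <- cps
  scaled$points[, c("X", "Y", "Z")] <- cps$points[, c("X", "Y", "Z")] * s
  fit_s <- estimate_dlt(scaled, "cam1")
  grid <- as.matrix(expand.grid(c(0.3, 1.1, 1.9), c(0.3, 1.7), c(0.2, 1.5)))
  expect_equal(reproject(fit_s, grid * s), reproject(fit, grid),
               tolerance = 1e-6)
})

test_that("reprojection RMSE grows monotonically with pixel noise", {
  sigmas <- c(0, 0.5, 1, 2)
  set.seed(99)
  means <- vapply(sigmas, function(s) {
    mean(replicate(20, estimate_dlt(cube_calibration_points(noise_sd = s),
                                    "cam0")$reprojection_rmse))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("triangulation inverts noise-free two-camera observations", {
  cams <- test_cameras()
  set.seed(7)
  pts <- cbind(runif(30, 0.5, 2.2), runif(30, 0.8, 2.7), runif(30, 0.1, 1.8))
  for (i in seq_len(nrow(pts))) {
    obs <- rbind(reproject(cams$cam0, pts[i, ]), reproject(cams$cam1, pts[i, ]))
    tri <- triangulate(obs, cams)
    expect_lt(max(abs(tri$xyz - pts[i, ])), 1e-9)
    expect_lt(tri$residual, 1e-9)
    expect_identical(tri$n_cameras, 2L)
  }
})

test_that("triangulation matches a nonlinear ray-intersection oracle", {
  cams <- test_cameras()
  set.seed(8)
  pts <- cbind(runif(10, 0.5, 2.2), runif(10, 0.8, 2.7), runif(10, 0.1, 1.8))
  for (i in seq_len(nrow(pts))) {
    obs <- rbind(reproject(cams$cam0, pts[i, ]), reproject(cams$cam1, pts[i, ]))
    tri <- triangulate(obs, cams)
    proj <- function(L, x) {
      den <- sum(L[9:11] * x) + 1
      if (den < 0.1) return(NULL)
      c((sum(L[1:3] * x) + L[4]) / den, (sum(L[5:7] * x) + L[8]) / den)
    }
    ref <- optim(pts[i, ] + 0.05, function(x) {
      p0 <- proj(cams$cam0, x)
      p1 <- proj(cams$cam1, x)
      if (is.null(p0) || is.null(p1)) return(1e8)
      sum((p0 - obs[1, ])^2 + (p1 - obs[2, ])^2)
    }, method = "BFGS", control = list(maxit = 2000, reltol = 1e-16))$par
    expect_lt(max(abs(tri$xyz - ref)), 1e-6)
  }
})

test_that("narrow baselines raise a conditioning warning", {
  # two cameras 1 degree apart as seen from the target
  ctr <- c(1.5, 1.75, 1.0)
  d <- 3
  a1 <- 0; a2 <- 1 * pi / 180
  cam_a <- dlt_from_pinhole(ctr + d * c(cos(a1), sin(a1), 0), ctr, 700)
  cam_b <- dlt_from_pinhole(ctr + d * c(cos(a2), sin(a2), 0), ctr, 700)
  p <- c(1.4, 1.9, 1.2)
  obs <- rbind(reproject(cam_a, p), reproject(cam_b, p))
  expect_warning(triangulate(obs, list(cam_a, cam_b)),
                 class = "conditioning_warning")
})

test_that("fewer than two usable cameras yield a missing mark, not an error", {
  cams <- test_cameras()
  p <- c(1.5, 1.75, 1.0)
  obs <- rbind(reproject(cams$cam0, p), reproject(cams$cam1, p))
  low_conf <- triangulate(obs, cams, confidence = c(0.9, 0.2))
  expect_true(all(is.na(low_conf$xyz)))
  expect_identical(low_conf$n_cameras, 1L)
  one_na <- triangulate(rbind(obs[1, ], NA), cams)
  expect_true(all(is.na(one_na$xyz)))
})

test_that("calibrations survive a JSON round trip", {
  fit <- estimate_dlt(cube_calibration_points(), "cam0")
  path <- tempfile(fileext = ".json")
  write_dlt_json(fit, path)
  back <- read_dlt_json(path)[[1]]
  expect_equal(back$L, fit$L, tolerance = 1e-12)
  expect_equal(back$camera_id, "cam0")
})
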