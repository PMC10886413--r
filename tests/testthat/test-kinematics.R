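# joint centers, toe offset, angles, cycles, distances

make_markerset <- function(cfg = sim_config(n_cycles = 3, pixel_noise_sd = 0,
                                            pixel_bias_amp = 0,
                                            marker_noise_sd = 0,
                                            soft_tissue_amp = 0, seed = 3)) {
  gt <- simulate_skier(cfg)
  list(gt = gt, mb = derive_markerbased(gt, cfg), cfg = cfg)
}

test_that("midpoint joint centers are exact midpoints", {
  fx <- make_markerset()
  jc <- joint_centers_from_markers(fx$mb$markers)
  knl <- fx$mb$markers$data[, "RKNL", ]
  knm <- fx$mb$markers$data[, "RKNM", ]
  expect_equal(jc$data[, "knee", ], (knl + knm) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("noise-free marker construction recovers the true joint centers", {
  fx <- make_markerset()
  jc <- joint_centers_from_markers(fx$mb$markers)
  for (p in c("wrist", "elbow", "shoulder", "hip", "knee", "ankle"))
    expect_lt(max(abs(jc$data[, p, ] - fx$gt$points[, p, ])), 1e-12)
  # toe differs exactly by the configured static mounting offset
  expect_equal(jc$data[, "toe", ] - fx$gt$points[, "toe", ],
               matrix(rep(fx$cfg$static_toe_offset / 1000,
                          each = nrow(jc$data)), ncol = 3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Bell hip offsets scale linearly with inter-ASIS distance", {
  hip0 <- c(1.4, 1.7, 1.0)
  bc <- bell_coefficients()
  for (d in c(0.20, 0.24, 0.30)) {
    mid <- hip0 - d * c(bc[["lateral"]], -bc[["posterior"]], -bc[["inferior"]])
    hjc <- skate3d:::bell_hip_center(rasi = mid + c(d / 2, 0, 0),
                                     lasi = mid - c(d / 2, 0, 0),
                                     sacr = mid - c(0, 0.13, 0))
    expect_equal(as.numeric(hjc), hip0, tolerance = 1e-12)
    # offset from the ASIS midpoint is exactly d * coefficients
    expect_equal(as.numeric(hjc) - mid,
                 d * c(bc[["lateral"]], -bc[["posterior"]], -bc[["inferior"]]),
                 tolerance = 1e-12)
  }
})

test_that("midpoint and Bell constructions are linear in marker coordinates", {
  fx1 <- make_markerset()
  set.seed(10)
  shift <- fx1$mb$markers
  delta <- array(rnorm(length(shift$data), 0, 0.01), dim(shift$data))
  sum_ms <- shift; sum_ms$data <- shift$data + delta
  jc1 <- joint_centers_from_markers(fx1$mb$markers)$data
  jc2 <- joint_centers_from_markers(sum_ms)$data
  # superposition for the strictly linear constructions (midpoints);
  # Bell is linear in rigid translations of the pelvis cluster
  half <- fx1$mb$markers; half$data <- fx1$mb$markers$data + delta / 2
  jc_half <- joint_centers_from_markers(half)$data
  for (p in c("wrist", "elbow", "shoulder", "knee", "ankle", "toe"))
    expect_equal(jc_half[, p, ], (jc1[, p, ] + jc2[, p, ]) / 2,
                 tolerance = 1e-10)
  tr <- fx1$mb$markers; tr$data <- sweep(tr$data, 3, -c(0.1, -0.2, 0.3))
  jc_tr <- joint_centers_from_markers(tr)$data
  expect_equal(sweep(jc_tr, 3, c(0.1, -0.2, 0.3)), jc1, tolerance = 1e-10)
})

test_that("missing pelvis markers make the hip unavailable", {
  fx <- make_markerset()
  ms <- fx$mb$markers
  keep <- setdiff(ms$markers, "SACR")
  ms$data <- ms$data[, keep, , drop = FALSE]
  ms$markers <- keep
  ms$gap_mask <- ms$gap_mask[, keep, drop = FALSE]
  expect_error(joint_centers_from_markers(ms), class = "marker_missing_error")
})

test_that("toe offset is recovered from static trials and removes dynamic bias", {
  # identical positions give a zero offset
  same <- matrix(rnorm(300), ncol = 3)
  off0 <- toe_offset_correction(same, same, rate = 100)
  expect_equal(as.numeric(off0), c(0, 0, 0))
  # constructed offset is recovered to noise / sqrt(frames)
  set.seed(6)
  ml <- matrix(rnorm(3 * 400, 0, 0.002), ncol = 3)
  mb <- sweep(ml, 2, -c(0, 0.030, 0.010)) +
    matrix(rnorm(3 * 400, 0, 0.002), ncol = 3)
  off <- toe_offset_correction(ml, mb, rate = 100)
  expect_lt(max(abs(as.numeric(off) - c(0, 0.030, 0.010))),
            6 * 0.002 * sqrt(2) / sqrt(400))
  expect_error(toe_offset_correction(ml[1:20, ], mb[1:20, ], rate = 100),
               class = "static_too_short_error")
})

test_that("joint vector angles follow their closed-form special cases", {
  mk <- function(wrist, elbow, shoulder, hip = c(0, 0, -1),
                 knee = c(0, 0, -2), ankle = c(0, 0, -3), toe = c(0, 1, -3)) {
    arr <- array(NA_real_, c(1, 7, 3),
                 dimnames = list(NULL, c("wrist", "elbow", "shoulder", "hip",
                                        "knee", "ankle", "toe"), NULL))
    arr[1, , ] <- rbind(wrist, elbow, shoulder, hip, knee, ankle, toe)
    arr
  }
  # collinear shoulder-elbow-wrist: fully extended arm, elbow angle 0
  a <- joint_vector_angles(mk(c(0, 0, 2), c(0, 0, 1), c(0, 0, 0)))
  expect_equal(as.numeric(a[1, "elbow"]), 0, tolerance = 1e-10)
  # forearm perpendicular to upper arm: 90 degrees
  a <- joint_vector_angles(mk(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0)))
  expect_equal(as.numeric(a[1, "elbow"]), 90, tolerance = 1e-10)
  # shank perpendicular to the foot: ankle angle 0 (complement of 90)
  a <- joint_vector_angles(mk(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0)))
  expect_equal(as.numeric(a[1, "ankle"]), 0, tolerance = 1e-10)
  # coincident points give an undefined-angle mark
  a <- joint_vector_angles(mk(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0)))
  expect_true(is.na(a[1, "elbow"]))
})

test_that("angles agree with an arccos oracle away from degeneracy", {
  set.seed(11)
  arccos_angle <- function(a, b)
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2))) * 180 / pi
  for (i in 1:100) {
    pts <- matrix(rnorm(21), 7, 3)
    dimnames(pts) <- list(c("wrist", "elbow", "shoulder", "hip", "knee",
                            "ankle", "toe"), NULL)
    arr <- array(pts, c(1, 7, 3), dimnames = c(list(NULL), dimnames(pts)))
    th <- arccos_angle(pts["wrist", ] - pts["elbow", ],
                       pts["shoulder", ] - pts["elbow", ])
    if (th > 1 && th < 179) {
      got <- joint_vector_angles(aperm(arr, c(1, 2, 3)))
      expect_equal(as.numeric(got[1, "elbow"]), 180 - th, tolerance = 1e-9)
    }
  }
})

test_that("angles are invariant under rigid motion and scaling", {
  fx <- make_markerset()
  base <- fx$gt$points[1:50, skate3d:::JOINT_POINTS, ]
  a0 <- joint_vector_angles(base)
  set.seed(12)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[3]), -sin(th[3])), c(0, sin(th[3]), cos(th[3])))
    R <- Rz %*% Ry %*% Rx
    tr <- runif(3, -2, 2)
    moved <- base
    for (p in seq_len(dim(base)[2]))
      moved[, p, ] <- sweep(base[, p, ] %*% t(R), 2, -tr)
    expect_equal(joint_vector_angles(moved), a0, tolerance = 1e-9)
  }
  ctr <- apply(base, 3, mean)
  scaled <- base
  for (p in seq_len(dim(base)[2]))
    scaled[, p, ] <- sweep(sweep(base[, p, ], 2, ctr) * 2, 2, -ctr)
  expect_equal(joint_vector_angles(scaled), a0, tolerance = 1e-9)
})

test_that("cycles segment on strikes and preserve structure", {
  # constant signal stays constant after normalization
  strikes <- seq(1L, 1101L, by = 100L)
  cs <- segment_cycles(rep(2.5, 1200), strikes, "G1", n_cycles = 10,
                       n_samples = 101)
  expect_equal(dim(cs$values), c(10, 101, 1))
  expect_true(all(cs$values == 2.5))
  # exactly periodic signal gives identical cycles
  t <- (0:1199) / 100
  x <- cbind(a = sin(2 * pi * t / 1.0), b = cos(2 * pi * t / 1.0))
  cs <- segment_cycles(x, strikes, "G1", n_cycles = 10)
  for (ci in 2:10)
    expect_equal(cs$values[ci, , ], cs$values[1, , ], tolerance = 1e-9)
  # endpoints are preserved and a linear signal keeps its cycle mean
  lin <- seq(0, 1, length.out = 1200)
  cs <- segment_cycles(lin, strikes, "G1", n_cycles = 10)
  expect_equal(unname(cs$values[1, 1, 1]), lin[1])
  expect_equal(unname(cs$values[1, 101, 1]), lin[101])
  expect_equal(mean(cs$values[1, , 1]), mean(lin[1:101]), tolerance = 1e-6)
})

test_that("G3 cycles span every second strike", {
  strikes <- seq(1L, 1441L, by = 60L)   # 25 strikes
  cs <- segment_cycles(sin((0:1500) / 20), strikes, "G3", n_cycles = 10)
  expect_equal(cs$boundaries, strikes[seq(1, 21, by = 2)])
  expect_error(segment_cycles(sin((0:1500) / 20), strikes[1:7], "G3",
                              n_cycles = 10),
               class = "insufficient_cycles_error")
})

test_that("G1 trials with 20 cycles yield 10 selected cycles on consecutive strikes", {
  cfg <- sim_config(technique = "G1", n_cycles = 20, pixel_noise_sd = 0,
                    pixel_bias_amp = 0, seed = 9)
  gt <- simulate_skier(cfg)
  cs <- segment_cycles(gt$angles, gt$strikes, "G1", n_cycles = 10)
  expect_equal(cs$n_cycles, 10)
  expect_equal(cs$n_samples, 101)
  expect_equal(cs$boundaries, gt$strikes[1:11])
})

test_that("euclidean distances follow the 3-4-5 construction", {
  cfg <- sim_config(n_cycles = 12, pixel_noise_sd = 0, pixel_bias_amp = 0,
                    marker_noise_sd = 0, soft_tissue_amp = 0, seed = 3)
  gt <- simulate_skier(cfg)
  jc <- list(rate = cfg$rate, data = gt$points[, skate3d:::JOINT_POINTS, ])
  class(jc) <- "joint_centers"
  a <- segment_cycles(jc, gt$strikes, cfg$technique, n_cycles = 5)
  expect_true(all(euclidean_distance_series(a, a) == 0))
  b <- a
  b$values <- sweep(a$values, 4, -c(0.003, 0.004, 0))
  d <- euclidean_distance_series(a, b)
  expect_equal(unname(range(d)), c(0.005, 0.005), tolerance = 1e-12)
  # mean of an injected error field is reproduced exactly
  set.seed(13)
  fld <- array(rnorm(length(a$values), 0, 0.01), dim(a$values))
  c2 <- a; c2$values <- a$values + fld
  d2 <- euclidean_distance_series(a, c2)
  expect_equal(mean(d2), mean(sqrt(apply(fld^2, c(1, 2, 3), sum))),
               tolerance = 1e-12)
  bad <- a; bad$items <- rev(a$items); dimnames(bad$values)[[3]] <- bad$items
  expect_error(euclidean_distance_series(a, bad), class = "label_error")
})
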