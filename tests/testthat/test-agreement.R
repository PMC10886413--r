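test_that("Bland-Altman handles degenerate and hand-computed cases", {
  ba0 <- bland_altman(rep(0, 10))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)
  expect_equal(unname(ba0$loa_classic), c(0, 0))
  expect_equal(unname(ba0$loa_tci), c(0, 0))

  ba <- bland_altman(c(1, -1), mode = "paired")
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(2), tolerance = 1e-9)
  expect_equal(unname(ba$loa_classic), c(-1.96 * sqrt(2), 1.96 * sqrt(2)),
               tolerance = 1e-9)
  expect_equal(unname(ba$loa_tci),
               c(-qt(0.975, 1) * sqrt(2) / sqrt(2), qt(0.975, 1) * sqrt(2) / sqrt(2)),
               tolerance = 1e-9)

  expect_error(bland_altman(3), class = "sample_size_error")
  expect_message(bland_altman(c(1, 2, NA, 4)), "1 non-finite")
})

test_that("large pooled samples reproduce the near-degenerate interval pattern", {
  set.seed(20)
  d <- rnorm(40000, 40.3, 30)
  ba <- bland_altman(d, mode = "one_sample")
  half_tci <- (ba$loa_tci[2] - ba$loa_tci[1]) / 2
  half_cls <- (ba$loa_classic[2] - ba$loa_classic[1]) / 2
  expect_equal(unname(half_tci), 1.96 * ba$sd / sqrt(40000), tolerance = 0.01)
  expect_equal(unname(half_cls), 1.96 * ba$sd, tolerance = 1e-9)
  # the t-based interval hugs the bias while the classical LoA does not
  expect_lt(half_tci, 0.5)
  expect_gt(half_cls, 50)
})

test_that("summary statistics match brute-force references on random instances", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    a <- rnorm(n, 10, 3)
    b <- a + rnorm(n, 1, 2)
    d <- a - b
    # loop-based oracles
    m <- 0; for (x in d) m <- m + x / n
    s2 <- 0; for (x in d) s2 <- s2 + (x - m)^2
    s <- sqrt(s2 / (n - 1))
    ba <- bland_altman(d, mode = "paired")
    expect_equal(ba$bias, m, tolerance = 1e-9)
    expect_equal(ba$sd, s, tolerance = 1e-9)
    expect_equal(unname(ba$loa_classic[2]), m + 1.96 * s, tolerance = 1e-9)
    expect_equal(unname(ba$loa_tci[1]), m - qt(0.975, n - 1) * s / sqrt(n),
                 tolerance = 1e-9)
    r2 <- 0; for (x in (a - b)) r2 <- r2 + x^2
    expect_equal(rmse(a, b), sqrt(r2 / n), tolerance = 1e-12)
    # textbook product-moment formula
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson(a, b)$r, num / den, tolerance = 1e-12)
  }
})

test_that("rmse identity links bias, SD and RMSE for paired differences", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- a - b
    ba <- bland_altman(d, mode = "paired")
    expect_equal(rmse(a, b)^2, ba$bias^2 + (n - 1) / n * ba$sd^2,
                 tolerance = 1e-10)
  }
})

test_that("rmse special cases and errors", {
  x <- rnorm(50)
  expect_identical(rmse(x, x), 0)
  expect_equal(rmse(x, x - 2.5), 2.5, tolerance = 1e-12)
  expect_error(rmse(1:3, 1:4), class = "length_error")
})

test_that("pearson handles affine relations, bands and errors", {
  x <- rnorm(30)
  p <- pearson(x, 2 * x + 1)
  expect_equal(p$r, 1, tolerance = 1e-12)
  expect_equal(pearson_band(0.96), "very high")
  expect_equal(pearson_band(0.82), "high")
  expect_equal(pearson_band(0.55), "moderate")
  expect_equal(pearson_band(0.1), "negligible")
  expect_error(pearson(x, rep(1, 30)), class = "zero_variance_error")
  expect_error(pearson(1:2, 2:3), class = "sample_size_error")
  # p-value matches cor.test
  set.seed(23)
  a <- rnorm(25); b <- a + rnorm(25, 0, 2)
  expect_equal(pearson(a, b)$p, cor.test(a, b)$p.value, tolerance = 1e-9)
})

test_that("ICC(A,1) matches trivial, simulated, and reference cases", {
  x <- rnorm(30, 5, 2)
  ident <- icc_a1(cbind(x, x))
  expect_equal(ident$icc, 1)
  expect_equal(ident$band, "excellent")

  set.seed(24)
  noise <- icc_a1(cbind(rnorm(1000), rnorm(1000)))
  expect_lt(abs(noise$icc), 0.1)

  expect_error(icc_a1(cbind(c(1, NA, 3, 4, 5), 1:5)),
               class = "incomplete_matrix_error")
  expect_error(icc_a1(cbind(1:4, 2:5)), class = "sample_size_error")
})

test_that("ICC(A,1) point estimate and CI match an external reference", {
  # fixtures regenerate the matrices that were scored with an independent
  # two-way absolute-agreement ICC implementation; its results are frozen
  frozen <- list(
    `20` = list(icc = 0.902227325212, ci = c(0.74, 0.96)),
    `12` = list(icc = 0.927211397939, ci = c(0.77, 0.98)),
    `50` = list(icc = 0.909684495315, ci = c(0.84, 0.95)))
  set.seed(101)
  for (n in c(20, 12, 50)) {
    a <- rnorm(n, 50, 10)
    b <- a + rnorm(n, 2, 4)
    got <- icc_a1(cbind(a, b))
    ref <- frozen[[as.character(n)]]
    expect_equal(got$icc, ref$icc, tolerance = 1e-9)
    expect_equal(round(unname(got$ci), 2), ref$ci)
  }
})

test_that("ICC tracks Pearson for exchangeable noise and drops under fixed bias", {
  set.seed(25)
  s <- rnorm(2000, 0, 10)
  a <- s + rnorm(2000, 0, 2)
  b <- s + rnorm(2000, 0, 2)
  icc_no_bias <- icc_a1(cbind(a, b))$icc
  r_no_bias <- pearson(a, b)$r
  expect_lt(abs(icc_no_bias - r_no_bias), 0.02)
  icc_bias <- icc_a1(cbind(a, b + 8))$icc
  expect_lt(icc_bias, pearson(a, b + 8)$r)
  expect_lt(icc_bias, icc_no_bias)
})

test_that("t-based interval shrinks with n while classical LoA stays put", {
  set.seed(26)
  widths <- vapply(c(1e2, 1e3, 1e4), function(n) {
    d <- rnorm(n, 5, 30)
    ba <- bland_altman(d)
    c(tci = unname(diff(ba$loa_tci)), cls = unname(diff(ba$loa_classic)) / ba$sd)
  }, numeric(2))
  expect_true(all(diff(widths["tci", ]) < 0))
  expect_equal(unname(widths["cls", ]), rep(2 * 1.96, 3), tolerance = 1e-9)
})

test_that("interpretation band edges follow the stated thresholds", {
  expect_equal(pearson_band(c(0.29, 0.30, 0.50, 0.70, 0.90)),
               c("negligible", "low", "moderate", "high", "very high"))
  expect_equal(icc_band(c(0.49, 0.50, 0.75, 0.90, 0.95)),
               c("poor", "moderate", "good", "excellent", "excellent"))
})

test_that("reports are pure functions of their inputs (byte-identical output)", {
  cfg <- sim_config(technique = "G3", n_cycles = 12, seed = 31)
  dir1 <- tempfile(); dir2 <- tempfile()
  end_to_end_fixture(cfg, dir1)
  res1 <- quiet(run_pipeline(file.path(dir1, "run.yaml")))
  rep1 <- res1$report
  f1 <- tempfile(fileext = ".json"); c1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".json"); c2 <- tempfile(fileext = ".csv")
  write_report(rep1, json = f1, angles_csv = c1)
  write_report(rep1, json = f2, angles_csv = c2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(c1), readLines(c2))
  # identical markerless/marker-based input gives the identity report
  same <- build_report(res1$cycles$ml, res1$cycles$ml)
  expect_true(all(same$distances$bias_mm == 0))
  expect_true(all(same$angles$bias_deg == 0))
  expect_true(all(same$angles$rmse_deg == 0))
  expect_equal(same$angles$icc, rep(1, 5), tolerance = 1e-12)
  expect_equal(same$angles$pearson_r, rep(1, 5), tolerance = 1e-12)
})
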