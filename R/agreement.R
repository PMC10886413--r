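# Method-agreement statistics: Bland-Altman, RMSE, Pearson, ICC(A,1).
#
# Two limits-of-agreement conventions are computed side by side.  The
# classical Bland-Altman 95% LoA is bias +/- 1.96 * SD of the differences
# and does not shrink with n.  A t-based 95% confidence interval of the
# bias (bias +/- t(0.975, n-1) * SD / sqrt(n)) shrinks like 1/sqrt(n) and
# becomes nearly degenerate around the bias for the tens of thousands of
# pooled samples a full comparison produces.  Both are reported and
# labeled: `loa_classic` and `loa_tci`.

#' Interpretation bands for correlation and ICC values
#'
#' Pearson coefficients are classified with thresholds 0.30 / 0.50 / 0.70 /
#' 0.90 into negligible, low, moderate, high and very high; ICCs with
#' thresholds 0.50 / 0.75 / 0.90 into poor, moderate, good and excellent.
#'
#' @param r,icc value to classify.
#' @return the band label as a character scalar.
#' @export
pearson_band <- function(r) {
  cut(r, breaks = c(-Inf, 0.30, 0.50, 0.70, 0.90, Inf),
      labels = c("negligible", "low", "moderate", "high", "very high"),
      right = FALSE) |> as.character()
}

#' @rdname pearson_band
#' @export
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE) |> as.character()
}

#' Bland-Altman summary of a difference series
#'
#' @param differences numeric vector of differences: per-sample Euclidean
#'   distances for joint centers (`mode = "one_sample"`, magnitudes) or
#'   signed markerless-minus-marker-based angle differences
#'   (`mode = "paired"`).  Non-finite values are dropped with a message.
#' @param mode labels which t-test flavor the bias test corresponds to;
#'   the summary statistics are identical.
#' @return object of class `bland_altman`: `bias` (mean difference), `sd`
#'   (sample SD, n-1), `loa_classic` (bias +/- 1.96 sd), `loa_tci` (t-based
#'   95% CI of the bias), `n`, `t`, `p`.
#' @export
bland_altman <- function(differences, mode = c("one_sample", "paired")) {
  mode <- match.arg(mode)
  d <- as.numeric(differences)
  bad <- !is.finite(d)
  if (any(bad)) {
    message(sprintf("bland_altman: excluding %d non-finite difference(s)", sum(bad)))
    d <- d[!bad]
  }
  n <- length(d)
  if (n < 2)
    stop_skate("Bland-Altman needs at least 2 finite differences, got %d", n,
               class = "sample_size_error")
  bias <- mean(d)
  s <- sd(d)
  half_tci <- qt(0.975, n - 1) * s / sqrt(n)
  tstat <- if (s > 0) bias / (s / sqrt(n)) else Inf * sign(bias)
  structure(list(bias = bias, sd = s,
                 loa_classic = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
                 loa_tci = c(lower = bias - half_tci, upper = bias + half_tci),
                 n = n, mode = mode, t = tstat,
                 p = 2 * pt(-abs(tstat), n - 1)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%s, n = %d)\n", x$mode, x$n))
  cat(sprintf("  bias %.4g, SD %.4g\n", x$bias, x$sd))
  cat(sprintf("  classical 95%% LoA: %.4g / %.4g\n",
              x$loa_classic[1], x$loa_classic[2]))
  cat(sprintf("  t-based 95%% CI of bias: %.4g / %.4g\n",
              x$loa_tci[1], x$loa_tci[2]))
  invisible(x)
}

#' Root mean squared error between two series
#'
#' @param a,b equal-length numeric vectors.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b))
    stop_skate("rmse: series lengths differ (%d vs %d)", length(a), length(b),
               class = "length_error")
  if (length(a) < 1)
    stop_skate("rmse: empty series", class = "length_error")
  sqrt(mean((a - b)^2))
}

#' Pearson correlation with significance and interpretation band
#'
#' @param a,b numeric vectors of equal length (n >= 3), both with nonzero
#'   variance.
#' @return object of class `pearson_validity`: `r`, two-sided `p` from the
#'   t transform, `n` and the interpretation `band`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b))
    stop_skate("pearson: series lengths differ", class = "length_error")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3)
    stop_skate("pearson: need at least 3 finite pairs, got %d", n,
               class = "sample_size_error")
  if (sd(a) == 0 || sd(b) == 0)
    stop_skate("pearson: undefined correlation, a series has zero variance",
               class = "zero_variance_error")
  r <- cor(a, b)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, p = 2 * pt(-abs(tstat), n - 2), n = n,
                 band = pearson_band(r)),
            class = "pearson_validity")
}

#' @export
print.pearson_validity <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (%s), p = %.3g, n = %d\n",
              x$r, x$band, x$p, x$n))
  invisible(x)
}

#' ICC(A,1): absolute-agreement intraclass correlation, single measurement
#'
#' Two-way ANOVA decomposition with rows as paired samples and columns as
#' measurement systems:
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The 95% confidence interval uses the standard F-based interval with a
#' Satterthwaite approximation for the denominator degrees of freedom.
#'
#' @param data n x k numeric matrix, one row per paired sample, one column
#'   per system (k = 2 for markerless vs marker-based); must be complete.
#' @param conf confidence level (default 0.95).
#' @return object of class `icc`: `icc`, `ci` (lower, upper), `band`, the
#'   mean squares, `n` and `k`.
#' @export
icc_a1 <- function(data, conf = 0.95) {
  m <- as.matrix(data)
  if (anyNA(m) || any(!is.finite(m)))
    stop_skate("icc_a1: matrix must be complete (no missing values)",
               class = "incomplete_matrix_error")
  n <- nrow(m); k <- ncol(m)
  if (n < 5 || k < 2)
    stop_skate("icc_a1: need at least 5 rows and 2 columns, got %d x %d",
               n, k, class = "sample_size_error")
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  SSR <- k * sum((rowm - gm)^2)
  SSC <- n * sum((colm - gm)^2)
  SST <- sum((m - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf
  if (abs(1 - icc) < 1e-12 || MSE == 0) {
    ci <- c(lower = icc, upper = icc)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower = lower, upper = upper)
  }
  structure(list(icc = icc, ci = ci, band = icc_band(icc),
                 MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%s), 95%% CI %.3f / %.3f, n = %d, k = %d\n",
              x$icc, x$band, x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}
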