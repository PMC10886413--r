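# Agreement reports: one table for joint-center / toe distances (mm) and
# one for joint vector angles (degrees, with RMSE / Pearson / ICC), plus
# per-sample mean +/- SD difference series for plotting.

#' Build a full markerless vs marker-based agreement report
#'
#' Pools every cycle and normalized time sample per item and technique.
#' Joint-center and toe placements are compared by 3D Euclidean distance
#' (one-sample Bland-Altman rows, reported in mm; distances are magnitudes,
#' so the "bias" is a mean magnitude, not a signed error).  Joint vector
#' angles are compared by signed difference (paired Bland-Altman rows in
#' degrees) plus RMSE, Pearson r with significance, and ICC(A,1) with its
#' 95% CI, each carrying its interpretation band.
#'
#' @param markerless,markerbased lists with elements `points` (a point
#'   `cycle_set`) and `angles` (a channel `cycle_set` of the five angles),
#'   from the same synchronized trial(s).
#' @param technique technique label; must match both cycle sets.
#' @return object of class `agreement_report` with data.frames `distances`
#'   (joint-center table) and `angles` (angle table), per-sample difference
#'   `series`, and metadata.
#' @export
build_report <- function(markerless, markerbased, technique = NULL) {
  for (side in list(markerless, markerbased))
    stopifnot(is.list(side), inherits(side$points, "cycle_set"),
              inherits(side$angles, "cycle_set"))
  techs <- c(markerless$points$technique, markerless$angles$technique,
             markerbased$points$technique, markerbased$angles$technique)
  technique <- technique %||% techs[1]
  if (!all(techs == technique))
    stop_skate("technique labels differ across cycle sets: %s",
               paste(unique(techs), collapse = ", "),
               class = "technique_mismatch_error")

  dist <- euclidean_distance_series(markerless$points, markerbased$points)
  pts <- dimnames(dist)[[3]]
  dist_rows <- lapply(pts, function(p) {
    ba <- bland_altman(as.numeric(dist[, , p]) * 1000, mode = "one_sample")
    data.frame(point = p, technique = technique,
               bias_mm = ba$bias, sd_mm = ba$sd,
               loa_tci_lower = ba$loa_tci[1], loa_tci_upper = ba$loa_tci[2],
               loa_classic_lower = ba$loa_classic[1],
               loa_classic_upper = ba$loa_classic[2],
               n = ba$n, row.names = NULL)
  })
  distances <- do.call(rbind, dist_rows)

  amv <- markerless$angles$values
  amb <- markerbased$angles$values
  if (!identical(dim(amv), dim(amb)) ||
      !identical(markerless$angles$items, markerbased$angles$items))
    stop_skate("angle cycle sets do not align", class = "label_error")
  angles_items <- markerless$angles$items
  ang_rows <- lapply(seq_along(angles_items), function(j) {
    a <- as.numeric(amv[, , j])
    b <- as.numeric(amb[, , j])
    keep <- is.finite(a) & is.finite(b)
    a <- a[keep]; b <- b[keep]
    ba <- bland_altman(a - b, mode = "paired")
    pr <- pearson(a, b)
    ic <- icc_a1(cbind(a, b))
    data.frame(angle = angles_items[j], technique = technique,
               bias_deg = ba$bias, sd_deg = ba$sd,
               loa_tci_lower = ba$loa_tci[1], loa_tci_upper = ba$loa_tci[2],
               loa_classic_lower = ba$loa_classic[1],
               loa_classic_upper = ba$loa_classic[2],
               rmse_deg = rmse(a, b),
               pearson_r = pr$r, pearson_p = pr$p, pearson_band = pr$band,
               icc = ic$icc, icc_lower = ic$ci[1], icc_upper = ic$ci[2],
               icc_band = ic$band, n = ba$n, row.names = NULL)
  })
  angles <- do.call(rbind, ang_rows)

  # Per-sample mean +/- SD difference curves across cycles
  pct <- seq(0, 100, length.out = markerless$points$n_samples)
  series_points <- lapply(pts, function(p) {
    d <- dist[, , p, drop = TRUE] * 1000
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    data.frame(pct = pct, mean = colMeans(d), sd = apply(d, 2, sd))
  })
  names(series_points) <- pts
  series_angles <- lapply(seq_along(angles_items), function(j) {
    d <- amv[, , j, drop = TRUE] - amb[, , j, drop = TRUE]
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    data.frame(pct = pct, mean = colMeans(d), sd = apply(d, 2, sd))
  })
  names(series_angles) <- angles_items

  structure(list(technique = technique, distances = distances, angles = angles,
                 series = list(points = series_points, angles = series_angles),
                 n_cycles = markerless$points$n_cycles,
                 n_samples = markerless$points$n_samples,
                 meta = list(pooling = "all cycles x samples",
                             distance_units = "mm", angle_units = "deg")),
            class = "agreement_report")
}

#' Merge agreement reports from several techniques
#'
#' @param ... `agreement_report` objects.
#' @return an `agreement_report` with stacked tables and concatenated series.
#' @export
merge_reports <- function(...) {
  reps <- list(...)
  if (length(reps) == 1 && is.list(reps[[1]]) &&
      !inherits(reps[[1]], "agreement_report")) reps <- reps[[1]]
  stopifnot(all(vapply(reps, inherits, logical(1), "agreement_report")))
  out <- reps[[1]]
  out$technique <- paste(vapply(reps, `[[`, character(1), "technique"),
                         collapse = "+")
  out$distances <- do.call(rbind, lapply(reps, `[[`, "distances"))
  out$angles <- do.call(rbind, lapply(reps, `[[`, "angles"))
  out$series <- lapply(reps, `[[`, "series")
  names(out$series) <- vapply(reps, `[[`, character(1), "technique")
  out
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement report (%s): %d cycles x %d samples pooled\n\n",
              x$technique, x$n_cycles, x$n_samples))
  cat("Joint centers and toe placements [mm]:\n")
  d <- x$distances
  print(data.frame(point = d$point, technique = d$technique,
                   bias = round(d$bias_mm, 1), sd = round(d$sd_mm, 1),
                   loa = sprintf("%.1f/%.1f", d$loa_tci_lower, d$loa_tci_upper)),
        row.names = FALSE)
  cat("\nJoint vector angles [deg]:\n")
  a <- x$angles
  print(data.frame(angle = a$angle, technique = a$technique,
                   bias = round(a$bias_deg, 2), sd = round(a$sd_deg, 2),
                   rmse = round(a$rmse_deg, 2),
                   r = round(a$pearson_r, 2), r_band = a$pearson_band,
                   icc = round(a$icc, 2), icc_band = a$icc_band),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.agreement_report <- function(object, ...) {
  cat(sprintf("Agreement report (%s)\n", object$technique))
  cat(sprintf("  mean joint-center distance: %.1f mm (range %.1f-%.1f)\n",
              mean(object$distances$bias_mm), min(object$distances$bias_mm),
              max(object$distances$bias_mm)))
  cat(sprintf("  angle bias range: %.2f to %.2f deg; RMSE range %.2f-%.2f deg\n",
              min(object$angles$bias_deg), max(object$angles$bias_deg),
              min(object$angles$rmse_deg), max(object$angles$rmse_deg)))
  cat(sprintf("  Pearson r range: %.2f-%.2f; ICC range: %.2f-%.2f\n",
              min(object$angles$pearson_r), max(object$angles$pearson_r),
              min(object$angles$icc), max(object$angles$icc)))
  invisible(object)
}

#' Plot mean +/- SD difference curves
#'
#' Draws the per-normalized-sample mean difference (black) with an SD band
#' (gray) for every joint-center distance and joint vector angle in the
#' report, one panel per item.
#'
#' @param x an `agreement_report`.
#' @param which `"points"`, `"angles"`, or `"both"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, which = c("both", "points", "angles"), ...) {
  which <- match.arg(which)
  series <- if (!is.null(x$series$points)) list(x$series) else x$series
  panels <- list()
  for (s in series) {
    if (which %in% c("both", "points"))
      for (p in names(s$points)) panels[[paste0(p, " [mm]")]] <- s$points[[p]]
    if (which %in% c("both", "angles"))
      for (p in names(s$angles)) panels[[paste0(p, " [deg]")]] <- s$angles[[p]]
  }
  nr <- ceiling(length(panels) / 3)
  op <- graphics::par(mfrow = c(nr, min(3, length(panels))),
                      mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  for (nm in names(panels)) {
    d <- panels[[nm]]
    ylim <- range(d$mean - d$sd, d$mean + d$sd)
    plot(d$pct, d$mean, type = "n", ylim = ylim,
         xlab = "cycle [%]", ylab = "difference", main = nm, ...)
    graphics::polygon(c(d$pct, rev(d$pct)),
                      c(d$mean - d$sd, rev(d$mean + d$sd)),
                      col = grDevices::grey(0.85), border = NA)
    graphics::lines(d$pct, d$mean, lwd = 2)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Write an agreement report to JSON and CSV
#'
#' Writers are deterministic: identical reports give byte-identical files.
#' Provenance (tool version, resolved configuration hash, input hashes) can
#' be attached and is embedded in the JSON and as `#` comment lines atop
#' the CSVs.
#'
#' @param report an `agreement_report`.
#' @param json,distances_csv,angles_csv output paths (`NULL` to skip).
#' @param provenance optional named list embedded in every output.
#' @export
write_report <- function(report, json = NULL, distances_csv = NULL,
                         angles_csv = NULL, provenance = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  if (!is.null(json)) {
    payload <- list(technique = report$technique,
                    n_cycles = report$n_cycles, n_samples = report$n_samples,
                    meta = report$meta, provenance = provenance,
                    distances = report$distances, angles = report$angles)
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE, dataframe = "rows")
  }
  write_table <- function(df, path) {
    hdr <- character(0)
    if (!is.null(provenance))
      hdr <- paste0("# ", names(provenance), ": ",
                    vapply(provenance, as.character, character(1)))
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(distances_csv)) write_table(report$distances, distances_csv)
  if (!is.null(angles_csv)) write_table(report$angles, angles_csv)
  invisible(report)
}
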