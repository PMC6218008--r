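# 6-significant-digit formatting shared by the CSV and TXT writers, so
# reruns are byte-identical
fmt6 <- function(x) sprintf("%.6g", x)

# fixed categorical palette, cycled by label -> reruns are visually identical
.label_palette <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00",
                    "#FFFF33", "#A65628", "#F781BF", "#66C2A5", "#FC8D62",
                    "#8DA0CB", "#E78AC3")

label_color <- function(label) {
  .label_palette[(label - 1L) %% length(.label_palette) + 1L]
}

#' Write the per-crack descriptor table
#'
#' One row per crack with columns `label, centroid_x, centroid_y, area_px,
#' area_um2, angle_deg, anisotropy, lambda1, lambda2, v1_x, v1_y, v2_x,
#' v2_y`; floats at 6 significant digits, comma-separated, '.' decimal,
#' UTF-8. An empty descriptor list produces a header-only file.
#'
#' @param descriptors list of `crack_descriptor`s from one image.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_crack_csv <- function(descriptors, path) {
  header <- paste(c("label", "centroid_x", "centroid_y", "area_px",
                    "area_um2", "angle_deg", "anisotropy",
                    "lambda1", "lambda2", "v1_x", "v1_y", "v2_x", "v2_y"),
                  collapse = ",")
  rows <- vapply(descriptors, function(d) {
    paste(c(d$label,
            fmt6(d$centroid[["x"]]), fmt6(d$centroid[["y"]]),
            d$area_px, fmt6(d$area_um2), fmt6(d$angle_deg),
            fmt6(d$anisotropy),
            fmt6(d$eigenvalues[["lambda1"]]), fmt6(d$eigenvalues[["lambda2"]]),
            fmt6(d$eigenvectors["x", "v1"]), fmt6(d$eigenvectors["y", "v1"]),
            fmt6(d$eigenvectors["x", "v2"]), fmt6(d$eigenvectors["y", "v2"])),
          collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, useBytes = TRUE)
  invisible(path)
}

#' Read back a descriptor CSV
#'
#' @param path CSV written by [write_crack_csv()].
#' @return A data frame with the writer's columns.
#' @export
read_crack_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Eigenvector cross segments for display
#'
#' The overlay draws each crack as a red cross: two orthogonal segments
#' through the centroid along the eigenvectors, each with half-length
#' `display_scale * sqrt(eigenvalue)` in pixel units (display_scale = 2
#' by default, purely a visual magnification).
#'
#' @param descriptor a `crack_descriptor`.
#' @param display_scale multiplier applied to `sqrt(lambda)`.
#' @return Data frame with one row per segment (`axis`, `x0`, `y0`, `x1`,
#'   `y1`, `half_length`), in pixel coordinates.
#' @export
vector_cross_segments <- function(descriptor, display_scale = 2) {
  cx <- descriptor$centroid[["x"]]; cy <- descriptor$centroid[["y"]]
  out <- lapply(1:2, function(j) {
    v <- descriptor$eigenvectors[, j]
    hl <- display_scale * sqrt(descriptor$eigenvalues[[j]])
    data.frame(axis = paste0("v", j),
               x0 = cx - hl * v[["x"]], y0 = cy - hl * v[["y"]],
               x1 = cx + hl * v[["x"]], y1 = cy + hl * v[["y"]],
               half_length = hl)
  })
  do.call(rbind, out)
}

open_figure <- function(path, width_in, height_in, format = c("pdf", "png")) {
  format <- match.arg(format)
  if (format == "pdf") {
    grDevices::pdf(path, width = width_in, height = height_in)
  } else {
    grDevices::png(path, width = round(72 * width_in),
                   height = round(72 * height_in))
  }
}

# draw an intensity image (matrix in [0,255]) as the figure canvas; returns
# nothing, leaves a coordinate system where pixel (row r, col c) has center
# (x = c - 0.5, y = h - r + 0.5)
draw_image_canvas <- function(px) {
  h <- nrow(px); w <- ncol(px)
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(0, h), asp = 1)
  graphics::rasterImage(px / 255, 0, 0, w, h, interpolate = FALSE)
}

to_plot_xy <- function(x_col, y_row, height) {
  list(x = x_col - 0.5, y = height - y_row + 0.5)
}

#' Render the three per-image overlay figures
#'
#' Writes (1) the intensity-inverted image, (2) the inverted image with a
#' per-label coloured overlay of the segmented cracks, and (3) the inverted
#' image with a red eigenvector cross per crack (half-lengths
#' `2 * sqrt(lambda)`, see [vector_cross_segments()]).
#'
#' @param image the [intensity_image()].
#' @param descriptors list of `crack_descriptor`s of that image.
#' @param regions matching list of `crack_region`s.
#' @param out_prefix path prefix; files are
#'   `<out_prefix>_{inverted,labels,vectors}.<ext>`.
#' @param format `"pdf"` (vector, default) or `"png"`.
#' @return Character vector of the three paths, invisibly.
#' @export
render_image_overlays <- function(image, descriptors, regions, out_prefix,
                                  format = "pdf") {
  stopifnot(inherits(image, "intensity_image"))
  inv <- 255L - image$pixels
  h <- image$height; w <- image$width
  size_in <- c(w, h) / 72
  paths <- paste0(out_prefix, "_", c("inverted", "labels", "vectors"),
                  ".", format)

  open_figure(paths[1], size_in[1], size_in[2], format)
  draw_image_canvas(inv)
  grDevices::dev.off()

  open_figure(paths[2], size_in[1], size_in[2], format)
  draw_image_canvas(inv)
  if (length(regions)) {
    overlay <- matrix("#00000000", h, w)
    for (reg in regions) {
      idx <- (reg$pixels[, "col"] - 1L) * h + reg$pixels[, "row"]
      overlay[idx] <- paste0(label_color(reg$label), "B0")
    }
    graphics::rasterImage(overlay, 0, 0, w, h, interpolate = FALSE)
  }
  grDevices::dev.off()

  open_figure(paths[3], size_in[1], size_in[2], format)
  draw_image_canvas(inv)
  for (d in descriptors) {
    seg <- vector_cross_segments(d)
    p0 <- to_plot_xy(seg$x0, seg$y0, h)
    p1 <- to_plot_xy(seg$x1, seg$y1, h)
    graphics::segments(p0$x, p0$y, p1$x, p1$y, col = "red", lwd = 1.5)
  }
  grDevices::dev.off()

  invisible(paths)
}

#' Render an axial polar histogram (orientation rose)
#'
#' Bars are mirrored to `[180, 360)` so the axial rose is symmetric. Bar
#' length is the weighted height; bar fill encodes the raw (unweighted)
#' count per bin on a viridis-like ramp, yellow for high counts and purple
#' for low.
#'
#' @param hist a [polar_histogram()], or `NULL` for an empty rose (image
#'   with no cracks).
#' @param path output file.
#' @param format `"pdf"` or `"png"`.
#' @param title optional figure title.
#' @return `path`, invisibly.
#' @export
render_polar_histogram <- function(hist, path, format = "pdf", title = NULL) {
  open_figure(path, 5, 5, format)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, if (is.null(title)) 1 else 3, 1))
  graphics::plot.new()
  rmax <- if (!is.null(hist) && max(hist$heights) > 0) max(hist$heights) else 1
  graphics::plot.window(xlim = c(-rmax, rmax) * 1.1,
                        ylim = c(-rmax, rmax) * 1.1, asp = 1)
  # grid circles and the 0/90 axes
  tt <- seq(0, 2 * pi, length.out = 181)
  for (f in c(0.5, 1)) {
    graphics::lines(rmax * f * cos(tt), rmax * f * sin(tt),
                    col = "grey80", lty = 3)
  }
  graphics::segments(-rmax, 0, rmax, 0, col = "grey70")
  graphics::segments(0, -rmax, 0, rmax, col = "grey70")
  if (!is.null(hist)) {
    ramp <- grDevices::hcl.colors(101, "viridis")  # purple -> yellow
    cmax <- max(hist$counts, 1)
    for (b in seq_len(hist$n_bins)) {
      if (hist$heights[b] <= 0) next
      col <- ramp[1 + round(100 * hist$counts[b] / cmax)]
      for (offset in c(0, 180)) {  # axial mirror
        a0 <- (hist$breaks_deg[b] + offset) * pi / 180
        a1 <- (hist$breaks_deg[b + 1] + offset) * pi / 180
        arc <- seq(a0, a1, length.out = 12)
        graphics::polygon(c(0, hist$heights[b] * cos(arc)),
                          c(0, hist$heights[b] * sin(arc)),
                          col = col, border = "grey30", lwd = 0.5)
      }
    }
  }
  if (!is.null(title)) graphics::title(main = title)
  invisible(path)
}

#' Write the per-series orientation summary
#'
#' One line per image (circular mean angle or NA, resultant vector length,
#' mean anisotropy) followed by a pooled block over all cracks of the
#' series: pooled circular mean, pooled R, pooled mean anisotropy, and the
#' Rao spacing test of orientation uniformity.
#'
#' @param per_image data frame with columns `image`, `mean_angle_deg`,
#'   `resultant_length`, `mean_anisotropy`, `n_cracks`.
#' @param pooled an `axial_summary` over the concatenated cracks.
#' @param rao a `rao_result` over the concatenated cracks, or `NULL` if the
#'   series has fewer than 4 cracks.
#' @param pooled_mean_anisotropy mean anisotropy over all cracks.
#' @param path destination TXT path.
#' @param series_name series label used in the heading.
#' @return `path`, invisibly.
#' @export
write_series_summary <- function(per_image, pooled, rao,
                                 pooled_mean_anisotropy, path,
                                 series_name = "series") {
  stopifnot(nrow(per_image) >= 1L)
  fmt_angle <- function(a, defined) {
    if (!defined || is.na(a)) "NA (undefined: resultant length ~ 0)"
    else sprintf("%.2f", a)
  }
  lines <- c(sprintf("Crack orientation summary - series '%s'", series_name),
             "",
             "Per image (circular mean angle [deg, 0-180], resultant vector length R [0-1], mean anisotropy):")
  for (i in seq_len(nrow(per_image))) {
    r <- per_image[i, ]
    lines <- c(lines, sprintf(
      "  %s: n_cracks = %d, mean_angle = %s, R = %s, mean_anisotropy = %s",
      r$image, r$n_cracks,
      fmt_angle(r$mean_angle_deg, !is.na(r$mean_angle_deg)),
      if (is.na(r$resultant_length)) "NA" else sprintf("%.3f", r$resultant_length),
      if (is.na(r$mean_anisotropy)) "NA" else sprintf("%.3f", r$mean_anisotropy)))
  }
  lines <- c(lines, "",
             "Global analysis (all cracks of the series pooled):",
             sprintf("  n_cracks = %d", pooled$n),
             sprintf("  pooled mean_angle = %s",
                     fmt_angle(pooled$mean_angle_deg, pooled$mean_defined)),
             sprintf("  pooled R = %.3f", pooled$resultant_length),
             sprintf("  pooled mean_anisotropy = %.3f", pooled_mean_anisotropy))
  if (!is.null(rao)) {
    lines <- c(lines,
               sprintf("  Rao spacing test: U = %.2f deg, critical value = %.2f deg (alpha = %.2f)",
                       rao$U_deg, rao$critical_value_deg, rao$alpha),
               sprintf("  decision: %s",
                       if (rao$significant)
                         "orientations are NOT uniform (significant angular bias)"
                       else "uniformity of orientations not rejected"))
  } else {
    lines <- c(lines,
               "  Rao spacing test: not run (fewer than 4 cracks in the series)")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Render the cross-series comparison outputs
#'
#' Writes a boxplot of per-image total crack areas (one box per series) and
#' a text summary listing, per pairwise comparison, both Shapiro p-values,
#' the Bartlett p-value (or n/a), the routed test, its statistic and
#' p-value. When more than two series are compared no multiple-testing
#' correction is applied; the text file states this.
#'
#' @param results list of `comparison_result`s from [compare_all_series()].
#' @param per_series_areas list of [series_areas()].
#' @param out_prefix path prefix; writes `<out_prefix>_boxplot.<ext>` and
#'   `<out_prefix>_tests.txt`.
#' @param format figure format, `"pdf"` or `"png"`.
#' @return Character vector of the two paths, invisibly.
#' @export
render_comparison <- function(results, per_series_areas, out_prefix,
                              format = "pdf") {
  stopifnot(length(per_series_areas) >= 2L)
  fig <- paste0(out_prefix, "_boxplot.", format)
  txt <- paste0(out_prefix, "_tests.txt")

  open_figure(fig, 5, 5, format)
  vals <- lapply(per_series_areas, `[[`, "totals_um2")
  names(vals) <- vapply(per_series_areas, `[[`, character(1), "series_name")
  graphics::par(mar = c(6, 4, 2, 1))
  graphics::boxplot(vals, las = 2, ylab = "total crack area per image (um^2)")
  grDevices::dev.off()

  lines <- c("Total crack area comparison (per-image totals, um^2)", "")
  for (res in results) {
    lines <- c(lines,
               sprintf("%s vs %s:", res$names[1], res$names[2]),
               sprintf("  Shapiro p (%s) = %s", res$names[1], fmt6(res$shapiro_p[1])),
               sprintf("  Shapiro p (%s) = %s", res$names[2], fmt6(res$shapiro_p[2])),
               sprintf("  Bartlett p = %s",
                       if (is.na(res$bartlett_p)) "n/a (non-normal route)"
                       else fmt6(res$bartlett_p)),
               sprintf("  chosen test = %s", res$chosen_test),
               sprintf("  statistic = %s", fmt6(res$statistic)),
               sprintf("  p-value = %s", fmt6(res$p_value)),
               "")
  }
  if (length(results) > 1L) {
    lines <- c(lines,
               "NOTE: multiple pairwise comparisons reported WITHOUT multiple-testing correction.")
  }
  con <- file(txt, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(c(fig, txt))
}
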