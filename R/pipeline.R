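#' Pipeline run configuration
#'
#' Mirrors the parameter block of the original workflow: the dataset root
#' (`updir`), the physical pixel size, the crack area window, the threshold
#' polarity, and the two global-analysis switches, plus a few extensions
#' (connectivity, histogram bin count, gate level, output format).
#'
#' @param updir dataset root directory: one subdirectory per sample series.
#' @param pixel_size physical pixel size in micrometres.
#' @param min_area_of_crack,max_area_of_crack inclusive crack area window
#'   in pixels; the lower bound removes speckle, the upper bound removes
#'   the image background.
#' @param threshold_type `"min"` (bright cracks, default) or `"max"` (dark
#'   cracks); the numeric threshold itself comes from each image filename.
#' @param global_output_size run the cross-series total-area comparison
#'   (default FALSE).
#' @param global_polarhist_output write per-series pooled polar histograms
#'   and orientation summaries (default FALSE).
#' @param connectivity component connectivity, 4 or 8.
#' @param n_bins polar histogram bin count over `[0, 180)`.
#' @param alpha significance level for the Shapiro/Bartlett gates and the
#'   Rao test.
#' @param output_format `"pdf"` (vector figures, default) or `"png"`.
#' @param anisotropy_formula passed to [shape_anisotropy()].
#' @return A `run_config` list.
#' @export
run_config <- function(updir, pixel_size = 1,
                       min_area_of_crack = 1, max_area_of_crack = Inf,
                       threshold_type = c("min", "max"),
                       global_output_size = FALSE,
                       global_polarhist_output = FALSE,
                       connectivity = 4, n_bins = 18, alpha = 0.05,
                       output_format = c("pdf", "png"),
                       anisotropy_formula = "normalized_difference") {
  threshold_type <- match.arg(threshold_type)
  output_format <- match.arg(output_format)
  stopifnot(pixel_size > 0, min_area_of_crack >= 1,
            max_area_of_crack >= min_area_of_crack,
            connectivity %in% c(4, 8), n_bins >= 2,
            alpha > 0, alpha < 1)
  structure(list(updir = updir, pixel_size = pixel_size,
                 min_area_of_crack = min_area_of_crack,
                 max_area_of_crack = max_area_of_crack,
                 threshold_type = threshold_type,
                 global_output_size = global_output_size,
                 global_polarhist_output = global_polarhist_output,
                 connectivity = connectivity, n_bins = n_bins, alpha = alpha,
                 output_format = output_format,
                 anisotropy_formula = anisotropy_formula),
            class = "run_config")
}

#' Run the full crack-quantification pipeline
#'
#' For every image of every series: segment with the filename-encoded
#' threshold, filter components by area, describe each surviving crack by
#' PCA, and write the per-crack CSV plus four figures (inverted image,
#' label overlay, eigenvector-cross overlay, per-image polar histogram)
#' next to the source image. With `global_polarhist_output`, each series
#' additionally gets a pooled polar histogram and an orientation summary
#' TXT (circular means, resultant lengths, mean anisotropy, Rao test).
#' With `global_output_size`, per-image total crack areas are compared
#' between all series pairs (routed Shapiro/Bartlett/t/Wilcoxon tree) with
#' a boxplot and a test summary written into `updir`.
#'
#' Orientations are only comparable across images if the images share a
#' consistent orientation; the pipeline reminds the user of this and does
#' not attempt registration.
#'
#' @param config a [run_config()].
#' @param quiet suppress per-image progress messages.
#' @return An `output_bundle`: list with `per_image` (data frame: path,
#'   series, threshold, n_cracks, total_area_um2, and per-image axial
#'   summary columns), `files` (all paths written), `comparisons` (list of
#'   `comparison_result`s or NULL), `n_failed` (images that errored and
#'   were skipped).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  say("note: orientation statistics assume all images of a series share a consistent orientation")
  index <- scan_dataset(config$updir)
  fmt <- config$output_format
  files <- character()
  rows <- list()
  series_cracks <- list()   # per series: list of descriptor lists per image
  n_failed <- 0L

  for (series in names(index$series)) {
    entries <- index$series[[series]]
    series_cracks[[series]] <- list()
    for (i in seq_len(nrow(entries))) {
      path <- entries$path[i]
      res <- tryCatch({
        img <- load_grayscale_image(path, pixel_size = config$pixel_size)
        params <- segmentation_params(
          threshold = entries$threshold[i],
          threshold_type = config$threshold_type,
          min_area_px = config$min_area_of_crack,
          max_area_px = config$max_area_of_crack,
          connectivity = config$connectivity)
        regions <- segment_cracks(img, params)
        descs <- describe_cracks(regions, pixel_size = config$pixel_size,
                                 anisotropy_formula = config$anisotropy_formula)
        stem <- tools::file_path_sans_ext(path)
        csv <- paste0(stem, "_cracks.csv")
        write_crack_csv(descs, csv)
        figs <- render_image_overlays(img, descs, regions, stem, format = fmt)
        ph_path <- paste0(stem, "_polarhist.", fmt)
        angles <- vapply(descs, `[[`, numeric(1), "angle_deg")
        if (length(angles)) {
          smp <- angle_sample(angles,
                              sqrt(vapply(descs, function(d)
                                d$eigenvalues[["lambda1"]], numeric(1))))
          render_polar_histogram(polar_histogram(smp, config$n_bins), ph_path,
                                 format = fmt, title = basename(stem))
          axs <- axial_mean_resultant(angle_sample(angles))
        } else {
          render_polar_histogram(NULL, ph_path, format = fmt,
                                 title = basename(stem))
          axs <- NULL
        }
        list(csv = csv, figs = figs, ph = ph_path, descs = descs, axs = axs)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        warning(sprintf("skipping %s: %s", path, conditionMessage(res)),
                call. = FALSE)
        next
      }
      files <- c(files, res$csv, res$figs, res$ph)
      series_cracks[[series]][[basename(path)]] <- res$descs
      anis <- vapply(res$descs, `[[`, numeric(1), "anisotropy")
      rows[[length(rows) + 1L]] <- data.frame(
        series = series, path = path, image = basename(path),
        threshold = entries$threshold[i],
        n_cracks = length(res$descs),
        total_area_um2 = sum(vapply(res$descs, `[[`, numeric(1), "area_um2")),
        mean_angle_deg = if (!is.null(res$axs) && res$axs$mean_defined)
          res$axs$mean_angle_deg else NA_real_,
        resultant_length = if (!is.null(res$axs))
          res$axs$resultant_length else NA_real_,
        mean_anisotropy = if (length(anis)) mean(anis) else NA_real_,
        stringsAsFactors = FALSE)
      say("%s: threshold %d -> %d crack(s) kept", path,
          entries$threshold[i], length(res$descs))
    }
  }
  per_image <- do.call(rbind, rows)
  if (is.null(per_image)) {
    stop("pipeline failed on every image", call. = FALSE)
  }

  if (config$global_polarhist_output) {
    for (series in names(series_cracks)) {
      descs <- unlist(series_cracks[[series]], recursive = FALSE)
      pi_rows <- per_image[per_image$series == series, , drop = FALSE]
      if (!nrow(pi_rows)) next
      base <- file.path(config$updir, series, paste0(series, "_series"))
      angles <- vapply(descs, `[[`, numeric(1), "angle_deg")
      if (length(angles)) {
        w <- sqrt(vapply(descs, function(d) d$eigenvalues[["lambda1"]],
                         numeric(1)))
        ph_path <- paste0(base, "_polarhist.", fmt)
        render_polar_histogram(polar_histogram(angle_sample(angles, w),
                                               config$n_bins),
                               ph_path, format = fmt, title = series)
        pooled <- axial_mean_resultant(angle_sample(angles))
        rao <- if (length(angles) >= 4)
          rao_spacing_test(angle_sample(angles), alpha = gate_alpha(config))
        else NULL
        anis <- mean(vapply(descs, `[[`, numeric(1), "anisotropy"))
      } else {
        ph_path <- paste0(base, "_polarhist.", fmt)
        render_polar_histogram(NULL, ph_path, format = fmt, title = series)
        pooled <- structure(list(mean_angle_deg = NA_real_,
                                 resultant_length = NA_real_, n = 0L,
                                 mean_defined = FALSE),
                            class = "axial_summary")
        rao <- NULL
        anis <- NA_real_
      }
      txt_path <- paste0(base, "_summary.txt")
      write_series_summary(pi_rows, pooled, rao, anis, txt_path,
                           series_name = series)
      files <- c(files, ph_path, txt_path)
    }
  }

  comparisons <- NULL
  if (config$global_output_size) {
    areas <- lapply(names(series_cracks), function(series) {
      series_areas(series,
                   per_image$total_area_um2[per_image$series == series])
    })
    if (length(areas) < 2L) {
      warning("global_output_size requested but fewer than 2 series present; skipping comparison",
              call. = FALSE)
    } else {
      comparisons <- compare_all_series(areas, alpha = gate_alpha(config))
      cmp_files <- render_comparison(comparisons, areas,
                                     file.path(config$updir, "crack_area"),
                                     format = fmt)
      files <- c(files, cmp_files)
    }
  }

  structure(list(per_image = per_image, files = files,
                 comparisons = comparisons, n_failed = n_failed),
            class = "output_bundle")
}

# rao/gate levels are snapped to the tabled values when needed
gate_alpha <- function(config) config$alpha

#' @export
print.output_bundle <- function(x, ...) {
  cat(sprintf("<output_bundle> %d image(s), %d file(s) written, %d failed\n",
              nrow(x$per_image), length(x$files), x$n_failed))
  invisible(x)
}
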