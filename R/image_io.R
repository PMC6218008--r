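#' Intensity image constructor
#'
#' An `intensity_image` is a 2D grid of 8-bit intensities together with the
#' physical pixel size. Pixel values are stored as an integer matrix in
#' `[0, 255]`, row 1 being the top image row.
#'
#' @param pixels integer matrix of intensities in `[0, 255]`.
#' @param pixel_size physical edge length of one pixel, in micrometres
#'   (strictly positive).
#' @param source provenance string (usually the file path).
#' @return An object of class `intensity_image` with fields `pixels`,
#'   `height`, `width`, `pixel_size`, `source`.
#' @export
intensity_image <- function(pixels, pixel_size = 1, source = "<memory>") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L) {
    stop("pixel intensities must be integers in [0, 255]", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (micrometres)",
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         pixel_size = as.numeric(pixel_size), source = source),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, pixel size %g um, source: %s\n",
              x$height, x$width, x$pixel_size, x$source))
  invisible(x)
}

img_ext <- function(path) tolower(tools::file_ext(path))

is_tiff_ext <- function(ext) ext %in% c("tif", "tiff")
is_jpeg_ext <- function(ext) ext %in% c("jpg", "jpeg")

#' Load a preprocessed 8-bit grayscale image
#'
#' Reads a single-channel 8-bit TIFF or grayscale JPEG. The protocol expects
#' images already preprocessed (8-bit conversion, contrast enhancement,
#' median smoothing); anything multi-channel or deeper than 8 bits is
#' rejected rather than silently converted, since conversion would change
#' the meaning of the filename-encoded threshold.
#'
#' @param path path to a `.tif`/`.tiff` or `.jpg`/`.jpeg` file.
#' @param pixel_size physical pixel size in micrometres.
#' @return An [intensity_image()]. 8-bit TIFF values are preserved
#'   bit-exactly.
#' @export
load_grayscale_image <- function(path, pixel_size = 1) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file does not exist: %s", path),
         call. = FALSE)
  }
  ext <- img_ext(path)
  if (is_tiff_ext(ext)) {
    raw <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                    error = function(e) {
                      stop(sprintf("I/O error reading TIFF %s: %s",
                                   path, conditionMessage(e)), call. = FALSE)
                    })
    bits <- attr(raw, "bits.per.sample")
    if (length(dim(raw)) == 3L) {
      stop(sprintf(
        "unsupported format: %s has %d channels; preprocess to a single-channel 8-bit grayscale image first",
        path, dim(raw)[3]), call. = FALSE)
    }
    if (!is.null(bits) && bits != 8L) {
      stop(sprintf(
        "unsupported format: %s is %d-bit; preprocess to 8-bit first (no silent conversion is performed)",
        path, bits), call. = FALSE)
    }
    px <- raw
  } else if (is_jpeg_ext(ext)) {
    raw <- tryCatch(jpeg::readJPEG(path),
                    error = function(e) {
                      stop(sprintf("I/O error reading JPEG %s: %s",
                                   path, conditionMessage(e)), call. = FALSE)
                    })
    if (length(dim(raw)) == 3L) {
      stop(sprintf(
        "unsupported format: %s has %d channels; save as grayscale JPEG first",
        path, dim(raw)[3]), call. = FALSE)
    }
    # JPEG decodes to [0,1] doubles; the codec is 8-bit so this is exact
    px <- round(raw * 255)
  } else {
    stop(sprintf("unsupported format: %s (expected .tif/.tiff/.jpg/.jpeg)",
                 path), call. = FALSE)
  }
  storage.mode(px) <- "integer"
  attributes(px) <- list(dim = dim(px))  # drop codec metadata
  intensity_image(px, pixel_size = pixel_size, source = path)
}

#' Save an intensity image
#'
#' Writes an 8-bit single-channel TIFF (bit-exact round trip) or a grayscale
#' JPEG at the given quality.
#'
#' @param image an [intensity_image()].
#' @param path destination path; format chosen from the extension.
#' @param quality JPEG quality in `(0, 1]`; ignored for TIFF.
#' @return `path`, invisibly.
#' @export
save_grayscale_image <- function(image, path, quality = 1) {
  stopifnot(inherits(image, "intensity_image"))
  ext <- img_ext(path)
  norm <- image$pixels / 255
  if (is_tiff_ext(ext)) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else if (is_jpeg_ext(ext)) {
    jpeg::writeJPEG(norm, path, quality = quality)
  } else {
    stop(sprintf("unsupported output format: %s", path), call. = FALSE)
  }
  invisible(path)
}

#' Parse the filename-encoded segmentation threshold
#'
#' Image filenames must end in `_XXXthld` before the extension, where `XXX`
#' is exactly three digits giving the per-image segmentation threshold
#' (e.g. `sample_1_162thld.tif` encodes threshold 162).
#'
#' @param filename a basename with a `.tif`/`.tiff`/`.jpg`/`.jpeg` extension
#'   (case-insensitive).
#' @return The threshold as an integer in `[0, 999]`.
#' @export
parse_threshold_from_filename <- function(filename) {
  stopifnot(is.character(filename), length(filename) == 1L)
  ext <- img_ext(filename)
  if (!(is_tiff_ext(ext) || is_jpeg_ext(ext))) {
    stop(sprintf(
      "naming-convention error: '%s' does not have a .tif/.tiff/.jpg/.jpeg extension",
      filename), call. = FALSE)
  }
  stem <- tools::file_path_sans_ext(basename(filename))
  m <- regmatches(stem, regexec("^.*_([0-9]{3})thld$", stem))[[1]]
  if (length(m) != 2L) {
    stop(sprintf(
      "naming-convention error: '%s' does not match '<name>_XXXthld.<ext>' with XXX exactly three digits",
      filename), call. = FALSE)
  }
  as.integer(m[2])
}

#' Index a two-level dataset directory
#'
#' The dataset root ("updir") contains one subdirectory per sample series
#' (e.g. different mutants or growth conditions), each holding the series'
#' images named `<name>_XXXthld.<ext>`. Only the first level of
#' subdirectories is traversed; non-conforming files are skipped with a
#' single warning listing them. Series and images are ordered
#' lexicographically so repeated scans are identical.
#'
#' @param root path to the dataset root directory.
#' @return A `dataset_index`: list with `root` and `series`, the latter a
#'   named list of data frames with columns `file`, `path`, `threshold`.
#' @export
scan_dataset <- function(root) {
  if (!dir.exists(root)) {
    stop(sprintf("dataset root does not exist: %s", root), call. = FALSE)
  }
  subdirs <- sort(list.dirs(root, full.names = TRUE, recursive = FALSE))
  series <- list()
  skipped <- character()
  for (d in subdirs) {
    files <- sort(list.files(d, full.names = FALSE, recursive = FALSE))
    files <- files[!dir.exists(file.path(d, files))]
    rows <- list()
    for (f in files) {
      thr <- tryCatch(parse_threshold_from_filename(f), error = function(e) NA)
      if (is.na(thr)) {
        skipped <- c(skipped, file.path(basename(d), f))
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(file = f, path = file.path(d, f), threshold = thr,
                     stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      series[[basename(d)]] <- do.call(rbind, rows)
    }
  }
  if (length(skipped)) {
    warning(sprintf("ignored %d non-conforming file(s): %s",
                    length(skipped), paste(skipped, collapse = ", ")),
            call. = FALSE)
  }
  if (!length(series)) {
    stop(sprintf(
      "empty dataset: no subdirectory of %s contains a conforming '_XXXthld' image",
      root), call. = FALSE)
  }
  structure(list(root = root, series = series), class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> root: %s\n", x$root))
  for (nm in names(x$series)) {
    cat(sprintf("  %s: %d image(s)\n", nm, nrow(x$series[[nm]])))
  }
  invisible(x)
}
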