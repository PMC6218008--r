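#' Segmentation parameters
#'
#' @param threshold intensity threshold in `[0, 255]`.
#' @param threshold_type `"min"` selects pixels at least as bright as the
#'   threshold (light cracks on a dark background); `"max"` selects pixels
#'   at most as dark (dark cracks). Comparisons are inclusive, matching the
#'   behaviour of the interactive threshold tool the protocol calibrates
#'   against.
#' @param min_area_px,max_area_px inclusive area window, in pixels. The
#'   lower bound removes speckle noise; the upper bound removes the image
#'   background when it satisfies the threshold.
#' @param connectivity pixel connectivity, 4 (edge neighbours, default) or
#'   8 (edge + corner neighbours).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(threshold, threshold_type = c("min", "max"),
                                min_area_px = 1, max_area_px = Inf,
                                connectivity = 4) {
  threshold_type <- match.arg(threshold_type)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 255) {
    stop("`threshold` must be a single value in [0, 255]", call. = FALSE)
  }
  if (min_area_px < 1 || max_area_px < min_area_px) {
    stop("need 1 <= min_area_px <= max_area_px", call. = FALSE)
  }
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  structure(list(threshold = as.integer(threshold),
                 threshold_type = threshold_type,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Threshold an image into a crack mask
#'
#' @param image an [intensity_image()] (or a bare integer matrix).
#' @param threshold intensity threshold in `[0, 255]`.
#' @param threshold_type `"min"`: mask is TRUE where intensity >= threshold;
#'   `"max"`: TRUE where intensity <= threshold.
#' @return A logical matrix of the image's shape.
#' @export
binarize <- function(image, threshold, threshold_type = c("min", "max")) {
  if (!is.character(threshold_type) ||
      !all(threshold_type %in% c("min", "max"))) {
    stop("configuration error: `threshold_type` must be \"min\" or \"max\"",
         call. = FALSE)
  }
  threshold_type <- match.arg(threshold_type)
  px <- if (inherits(image, "intensity_image")) image$pixels else image
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must be in [0, 255]", call. = FALSE)
  }
  if (threshold_type == "min") px >= threshold else px <= threshold
}

# Label connected components of a logical mask. Components are found on the
# pixel-adjacency graph (igraph); labels are then re-assigned 1..k in
# raster-scan order (top row first, left to right) of each component's first
# pixel, so labelling is deterministic regardless of the traversal order.
label_mask <- function(mask, connectivity = 4) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)  # column-major linear indices of foreground pixels
  if (!length(idx)) return(lab)
  fg <- logical(nr * nc); fg[idx] <- TRUE
  vert <- integer(nr * nc); vert[idx] <- seq_along(idx)

  edge_pairs <- function(di, dj) {
    r <- (idx - 1L) %% nr + 1L
    co <- (idx - 1L) %/% nr + 1L
    r2 <- r + di; c2 <- co + dj
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- fg[nb]
    cbind(vert[idx[ok][keep]], vert[nb[keep]])
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(offs, function(o) edge_pairs(o[1], o[2])))

  g <- igraph::graph_from_edgelist(
    matrix(as.numeric(edges), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(idx)]

  # raster-scan order of each component's first pixel
  raster <- ((idx - 1L) %% nr) * nc + ((idx - 1L) %/% nr)  # row-major rank
  first <- tapply(raster, comp, min)
  relab <- integer(length(first))
  relab[order(first)] <- seq_along(first)
  lab[idx] <- relab[comp]
  lab
}

#' Extract area-filtered crack regions from a binary mask
#'
#' Finds connected components under the configured connectivity and keeps
#' those whose pixel area lies inside the inclusive
#' `[min_area_px, max_area_px]` window. Surviving regions are labelled
#' `1..k` in raster-scan order of each region's first pixel.
#'
#' @param mask logical matrix from [binarize()].
#' @param params a [segmentation_params()].
#' @return A list of `crack_region` objects, each with fields `label`,
#'   `pixels` (two-column matrix of (row, col) coordinates) and `area_px`.
#' @export
extract_regions <- function(mask, params) {
  stopifnot(inherits(params, "segmentation_params"))
  lab <- label_mask(mask, params$connectivity)
  k <- max(lab)
  if (k == 0L) return(list())
  areas <- tabulate(lab[lab > 0L], nbins = k)
  keep <- which(areas >= params$min_area_px & areas <= params$max_area_px)
  regions <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    idx <- which(lab == keep[i])
    nr <- nrow(mask)
    pix <- cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
    regions[[i]] <- structure(
      list(label = i, pixels = pix, area_px = nrow(pix)),
      class = "crack_region")
  }
  regions
}

#' @export
print.crack_region <- function(x, ...) {
  cat(sprintf("<crack_region> label %d, %d px\n", x$label, x$area_px))
  invisible(x)
}

#' Segment an intensity image into crack regions
#'
#' Convenience wrapper: [binarize()] then [extract_regions()].
#'
#' @inheritParams binarize
#' @param params a [segmentation_params()]; its threshold and polarity are
#'   used for the binarization.
#' @return A list of `crack_region` objects.
#' @export
segment_cracks <- function(image, params) {
  mask <- binarize(image, params$threshold, params$threshold_type)
  extract_regions(mask, params)
}
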