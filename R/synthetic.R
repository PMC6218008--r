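#' Specification of one synthetic crack
#'
#' Cracks are modelled as filled ellipses: they have closed-form area,
#' orientation and anisotropy, and rasterize to closed domains like the
#' bright cell-separation regions the pipeline targets.
#'
#' @param center c(x, y) centre in pixel coordinates (x = column, y = row).
#' @param semi_major,semi_minor ellipse semi-axes in pixels
#'   (`semi_major >= semi_minor > 0`).
#' @param orientation_deg major-axis orientation in `[0, 180)`, same screen
#'   convention as [principal_angle()].
#' @param intensity crack pixel intensity in `[0, 255]`.
#' @return A `crack_spec` list.
#' @export
crack_spec <- function(center, semi_major, semi_minor, orientation_deg,
                       intensity) {
  stopifnot(length(center) == 2L, semi_minor > 0,
            semi_major >= semi_minor,
            orientation_deg >= 0, orientation_deg < 180,
            intensity >= 0, intensity <= 255)
  structure(list(center = c(x = center[[1]], y = center[[2]]),
                 semi_major = semi_major, semi_minor = semi_minor,
                 orientation_deg = orientation_deg,
                 intensity = as.integer(intensity)),
            class = "crack_spec")
}

#' Specification of one synthetic scene
#'
#' A scene is a background of constant intensity carrying non-overlapping
#' elliptical cracks, with optional additive Gaussian noise (clipped to
#' `[0, 255]` and rounded). Crack interiors must be pairwise disjoint and
#' not even corner-adjacent (8-connectivity), so each crack is a separate
#' closed domain for the component labelling.
#'
#' @param width,height image size in pixels.
#' @param cracks list of [crack_spec()]s.
#' @param background_intensity background level in `[0, 255]`.
#' @param noise_sigma standard deviation of the additive Gaussian noise
#'   (0 for a noise-free scene).
#' @param seed integer seed making the noise reproducible.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width, height, cracks,
                       background_intensity = 20, noise_sigma = 0,
                       seed = 1L) {
  stopifnot(width >= 1, height >= 1, noise_sigma >= 0,
            background_intensity >= 0, background_intensity <= 255)
  if (!length(cracks) || !all(vapply(cracks, inherits, TRUE, "crack_spec"))) {
    stop("`cracks` must be a non-empty list of crack_spec", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 cracks = cracks,
                 background_intensity = as.integer(background_intensity),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# Rasterize one ellipse: a pixel belongs to the crack iff its integer
# center (col = x, row = y) satisfies the ellipse inequality. Returns a
# two-column (row, col) matrix.
rasterize_ellipse <- function(spec, width, height) {
  th <- spec$orientation_deg * pi / 180
  # bounding box in pixel coords
  r <- max(spec$semi_major, spec$semi_minor)
  cols <- max(1L, floor(spec$center[["x"]] - r)):min(width, ceiling(spec$center[["x"]] + r))
  rows <- max(1L, floor(spec$center[["y"]] - r)):min(height, ceiling(spec$center[["y"]] + r))
  grid <- expand.grid(row = rows, col = cols)
  dcol <- grid$col - spec$center[["x"]]
  drow <- grid$row - spec$center[["y"]]
  # screen convention: y-up axis is -row
  m <- dcol * cos(th) - drow * sin(th)   # along major axis
  s <- -dcol * sin(th) - drow * cos(th)  # along minor axis
  inside <- (m / spec$semi_major)^2 + (s / spec$semi_minor)^2 <= 1
  as.matrix(grid[inside, c("row", "col"), drop = FALSE])
}

# run a block with a local RNG state so generators are seeded without
# disturbing the caller's random stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a ground-truthed synthetic crack image
#'
#' Rasterizes every crack of the scene over the background, adds seeded
#' Gaussian noise, clips to `[0, 255]` and rounds. The returned ground
#' truth records, per crack, the exact rasterized pixel set and area plus
#' the nominal orientation and the angle/anisotropy of the rasterized pixel
#' set (computed from its coordinate covariance, so recovery tests compare
#' like with like).
#'
#' @param scene a [scene_spec()].
#' @param pixel_size physical pixel size forwarded to the image.
#' @return List with `image` (an [intensity_image()]) and `truth`, a list
#'   of per-crack records (`pixels`, `area_px`, `orientation_deg`,
#'   `angle_deg`, `anisotropy`, `intensity`, `center`).
#' @export
generate_crack_image <- function(scene, pixel_size = 1) {
  stopifnot(inherits(scene, "scene_spec"))
  rasters <- lapply(scene$cracks, rasterize_ellipse,
                    width = scene$width, height = scene$height)
  if (any(vapply(rasters, nrow, 1L) == 0L)) {
    stop("crack rasterizes to zero pixels inside the image", call. = FALSE)
  }
  # disjointness incl. 8-adjacency: dilate each crack's pixel set by one and
  # check against the other cracks' pixels
  occ <- matrix(0L, scene$height, scene$width)
  for (i in seq_along(rasters)) {
    idx <- (rasters[[i]][, "col"] - 1L) * scene$height + rasters[[i]][, "row"]
    if (any(occ[idx] != 0L)) {
      stop("spec violation: crack interiors overlap", call. = FALSE)
    }
    occ[idx] <- i
  }
  for (i in seq_along(rasters)) {
    px <- rasters[[i]]
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- px[, "row"] + dr; c2 <- px[, "col"] + dc
      ok <- r2 >= 1L & r2 <= scene$height & c2 >= 1L & c2 <= scene$width
      nb <- occ[(c2[ok] - 1L) * scene$height + r2[ok]]
      if (any(nb != 0L & nb != i)) {
        stop("spec violation: cracks touch under 8-connectivity", call. = FALSE)
      }
    }
  }
  px <- matrix(as.numeric(scene$background_intensity),
               scene$height, scene$width)
  for (i in seq_along(rasters)) {
    idx <- (rasters[[i]][, "col"] - 1L) * scene$height + rasters[[i]][, "row"]
    px[idx] <- scene$cracks[[i]]$intensity
  }
  if (scene$noise_sigma > 0) {
    noise <- with_local_seed(scene$seed,
                             rnorm(length(px), sd = scene$noise_sigma))
    px <- px + noise
  }
  px <- matrix(as.integer(pmin(255, pmax(0, round(px)))),
               scene$height, scene$width)
  img <- intensity_image(px, pixel_size = pixel_size,
                         source = sprintf("<synthetic seed %d>", scene$seed))
  truth <- lapply(seq_along(rasters), function(i) {
    reg <- structure(list(label = i, pixels = rasters[[i]],
                          area_px = nrow(rasters[[i]])),
                     class = "crack_region")
    pa <- principal_axes(reg)
    list(pixels = rasters[[i]], area_px = nrow(rasters[[i]]),
         orientation_deg = scene$cracks[[i]]$orientation_deg,
         angle_deg = principal_angle(pa$eigenvectors[, "v1"]),
         anisotropy = shape_anisotropy(pa$eigenvalues[["lambda1"]],
                                       pa$eigenvalues[["lambda2"]]),
         intensity = scene$cracks[[i]]$intensity,
         center = scene$cracks[[i]]$center)
  })
  list(image = img, truth = truth)
}

#' Write a synthetic dataset tree
#'
#' Materialises scenes as a two-level dataset: one subdirectory per series,
#' each image written as an 8-bit TIFF named `<name>_XXXthld.tif` plus a
#' plain-text ground-truth sidecar `<name>_XXXthld_truth.csv` (per-crack
#' area, orientation, rasterized angle/anisotropy). [scan_dataset()] on the
#' result reproduces the layout.
#'
#' @param layout named list: series name -> named list of [scene_spec()]s
#'   (names become image stems).
#' @param thresholds integer in `[0, 999]`, recycled over all images; the
#'   filename-encoded segmentation threshold.
#' @param root destination directory.
#' @param pixel_size forwarded to the generated images.
#' @param overwrite allow writing into an existing non-empty `root`.
#' @return Invisibly, a data frame of written image paths with their series
#'   and threshold.
#' @export
generate_dataset <- function(layout, thresholds, root, pixel_size = 1,
                             overwrite = FALSE) {
  if (!length(layout)) stop("empty dataset layout", call. = FALSE)
  if (any(thresholds < 0 | thresholds > 999 | thresholds != floor(thresholds))) {
    stop("thresholds must be integers in [0, 999] (three digits)", call. = FALSE)
  }
  if (dir.exists(root) && length(list.files(root)) && !overwrite) {
    stop(sprintf("refusing to write into non-empty directory %s (set overwrite = TRUE)",
                 root), call. = FALSE)
  }
  n_img <- sum(lengths(layout))
  thresholds <- rep_len(as.integer(thresholds), n_img)
  rows <- list(); k <- 0L
  for (series in names(layout)) {
    dir.create(file.path(root, series), recursive = TRUE, showWarnings = FALSE)
    scenes <- layout[[series]]
    if (is.null(names(scenes)) || any(!nzchar(names(scenes)))) {
      stop("every scene needs a name (the image stem)", call. = FALSE)
    }
    for (nm in names(scenes)) {
      k <- k + 1L
      thr <- thresholds[k]
      stem <- sprintf("%s_%03dthld", nm, thr)
      path <- file.path(root, series, paste0(stem, ".tif"))
      gen <- generate_crack_image(scenes[[nm]], pixel_size = pixel_size)
      save_grayscale_image(gen$image, path)
      truth_df <- do.call(rbind, lapply(seq_along(gen$truth), function(i) {
        tr <- gen$truth[[i]]
        data.frame(crack = i, center_x = tr$center[["x"]],
                   center_y = tr$center[["y"]], area_px = tr$area_px,
                   orientation_deg = tr$orientation_deg,
                   raster_angle_deg = tr$angle_deg,
                   raster_anisotropy = tr$anisotropy,
                   intensity = tr$intensity)
      }))
      utils::write.csv(truth_df,
                       file.path(root, series, paste0(stem, "_truth.csv")),
                       row.names = FALSE)
      rows[[k]] <- data.frame(series = series, path = path, threshold = thr,
                              stringsAsFactors = FALSE)
    }
  }
  invisible(do.call(rbind, rows))
}
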