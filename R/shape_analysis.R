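#' Principal axes of a crack region
#'
#' Computes the centroid and the eigen-decomposition of the 2x2 population
#' covariance matrix (divisor N: the region is the complete pixel set, not
#' a sample) of the region's pixel coordinates, in (x = column, y = row)
#' image coordinates. Eigenvalues are sorted descending; eigenvectors are
#' unit-norm with a deterministic sign: non-negative x-component, and if
#' the x-component is zero, non-negative y-component. A single pixel has
#' zero covariance and gets `v1 = (1, 0)` by convention.
#'
#' @param region a `crack_region` from [extract_regions()].
#' @return List with `centroid` (named c(x, y)), `eigenvalues`
#'   (c(lambda1, lambda2), px^2) and `eigenvectors` (2x2 matrix, columns
#'   v1, v2 in (x, y) components).
#' @export
principal_axes <- function(region) {
  stopifnot(inherits(region, "crack_region"), nrow(region$pixels) >= 1L)
  xy <- cbind(x = as.numeric(region$pixels[, "col"]),
              y = as.numeric(region$pixels[, "row"]))
  n <- nrow(xy)
  mu <- colMeans(xy)
  centered <- sweep(xy, 2, mu)
  covm <- crossprod(centered) / n
  ev <- eigen(covm, symmetric = TRUE)
  vals <- pmax(ev$values, 0)  # clip tiny negative rounding
  vecs <- ev$vectors
  # exact eigenvalue tie (isotropic region, incl. single pixel): the basis
  # is arbitrary, so fix the axis-aligned one -> angle 0 by convention
  if (vals[1] == vals[2]) vecs <- diag(2)
  for (j in 1:2) {
    v <- vecs[, j]
    if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) vecs[, j] <- -v
  }
  dimnames(vecs) <- list(c("x", "y"), c("v1", "v2"))
  list(centroid = c(x = unname(mu[1]), y = unname(mu[2])),
       eigenvalues = c(lambda1 = vals[1], lambda2 = vals[2]),
       eigenvectors = vecs)
}

#' Principal orientation angle of a crack
#'
#' Orientation of the leading eigenvector, measured counter-clockwise from
#' the horizontal in the displayed image. Image rows grow downwards, so in
#' (x = column, y = row) components the angle is
#' `atan2(-v1_y, v1_x)` reduced modulo 180 into `[0, 180)`: a horizontal
#' crack is 0 degrees, a vertical one 90 degrees.
#'
#' @param v1 leading eigenvector as c(x, y) components (unit norm).
#' @return Angle in degrees in `[0, 180)`.
#' @export
principal_angle <- function(v1) {
  stopifnot(length(v1) == 2L)
  (atan2(-v1[[2]], v1[[1]]) * 180 / pi) %% 180
}

#' Shape anisotropy from covariance eigenvalues
#'
#' The default is the normalized eigenvalue difference
#' `(lambda1 - lambda2) / (lambda1 + lambda2)`: 0 for an isotropic blob,
#' 1 for a perfect line, invariant to rotation and scale. The alternative
#' `1 - lambda2 / lambda1` is available for matching other conventions.
#' A zero-covariance region (single pixel) returns 0.
#'
#' @param lambda1,lambda2 covariance eigenvalues with
#'   `lambda1 >= lambda2 >= 0`.
#' @param formula `"normalized_difference"` (default) or
#'   `"one_minus_ratio"`.
#' @return Anisotropy in `[0, 1]`.
#' @export
shape_anisotropy <- function(lambda1, lambda2,
                             formula = c("normalized_difference",
                                         "one_minus_ratio")) {
  formula <- match.arg(formula)
  if (lambda2 < 0 || lambda1 < lambda2) {
    stop("contract violation: need lambda1 >= lambda2 >= 0", call. = FALSE)
  }
  if (lambda1 + lambda2 == 0) return(0)
  switch(formula,
         normalized_difference = (lambda1 - lambda2) / (lambda1 + lambda2),
         one_minus_ratio = 1 - lambda2 / lambda1)
}

#' Full per-crack shape descriptor
#'
#' Assembles the CSV row for one crack: label, centroid (x = column,
#' y = row, pixel units), areas in px and um^2 (`area_px * pixel_size^2`),
#' principal angle, shape anisotropy, eigenvalues and eigenvectors.
#'
#' @param region a `crack_region`.
#' @param pixel_size physical pixel size in micrometres.
#' @param anisotropy_formula passed to [shape_anisotropy()].
#' @return A `crack_descriptor` list.
#' @export
describe_crack <- function(region, pixel_size = 1,
                           anisotropy_formula = "normalized_difference") {
  stopifnot(pixel_size > 0)
  pa <- principal_axes(region)
  l1 <- pa$eigenvalues[["lambda1"]]
  l2 <- pa$eigenvalues[["lambda2"]]
  structure(list(
    label = region$label,
    centroid = pa$centroid,
    area_px = region$area_px,
    area_um2 = region$area_px * pixel_size^2,
    angle_deg = principal_angle(pa$eigenvectors[, "v1"]),
    anisotropy = shape_anisotropy(l1, l2, anisotropy_formula),
    eigenvalues = pa$eigenvalues,
    eigenvectors = pa$eigenvectors
  ), class = "crack_descriptor")
}

#' @export
print.crack_descriptor <- function(x, ...) {
  cat(sprintf(
    "<crack_descriptor> label %d: area %d px (%.4g um^2), angle %.2f deg, anisotropy %.3f\n",
    x$label, x$area_px, x$area_um2, x$angle_deg, x$anisotropy))
  invisible(x)
}

#' Descriptor table for one image
#'
#' @param regions list of `crack_region`s from one image.
#' @param pixel_size physical pixel size in micrometres.
#' @param anisotropy_formula passed to [shape_anisotropy()].
#' @return List of `crack_descriptor`s (possibly empty).
#' @export
describe_cracks <- function(regions, pixel_size = 1,
                            anisotropy_formula = "normalized_difference") {
  lapply(regions, describe_crack, pixel_size = pixel_size,
         anisotropy_formula = anisotropy_formula)
}
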