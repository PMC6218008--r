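#' Weighted sample of axial angles
#'
#' Crack orientations are axial: a crack at 10 degrees is the same crack as
#' one at 190 degrees. Input angles are reduced modulo 180 into `[0, 180)`.
#' Weights default to 1; in the polar histograms the weight of each
#' orientation is the square root of the crack's principal eigenvalue, so
#' long cracks contribute proportionally to their extent.
#'
#' @param angles_deg numeric vector of orientations in degrees.
#' @param weights non-negative weights, recycled to the length of
#'   `angles_deg`; at least one must be positive.
#' @return An `angle_sample` with fields `angles_deg` (reduced to
#'   `[0, 180)`) and `weights`.
#' @export
angle_sample <- function(angles_deg, weights = 1) {
  if (!length(angles_deg)) {
    stop("empty angle sample", call. = FALSE)
  }
  if (anyNA(angles_deg)) stop("angles must not contain NA", call. = FALSE)
  weights <- rep_len(weights, length(angles_deg))
  if (anyNA(weights) || any(weights < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (all(weights == 0)) {
    stop("at least one weight must be positive", call. = FALSE)
  }
  structure(list(angles_deg = angles_deg %% 180, weights = weights),
            class = "angle_sample")
}

#' Axial circular mean and resultant vector length
#'
#' Angles are doubled onto the full circle (the standard axial correction),
#' the weighted mean resultant vector is computed there, and the mean
#' direction is halved back. The resultant length R lies in `[0, 1]`:
#' 1 when all cracks share one orientation, 0 when orientations are spread
#' homogeneously. When R is numerically zero (below `tol`) the mean angle
#' is undefined and reported as `NA`.
#'
#' @param sample an [angle_sample()].
#' @param tol resultant length below which the mean is flagged undefined.
#' @return An `axial_summary` with `mean_angle_deg` (in `[0, 180)` or NA),
#'   `resultant_length`, `n`, `mean_defined`.
#' @export
axial_mean_resultant <- function(sample, tol = 1e-9) {
  stopifnot(inherits(sample, "angle_sample"))
  th2 <- 2 * sample$angles_deg * pi / 180
  w <- sample$weights
  C <- sum(w * cos(th2)) / sum(w)
  S <- sum(w * sin(th2)) / sum(w)
  R <- sqrt(C^2 + S^2)
  defined <- R >= tol
  mean_deg <- if (defined) (atan2(S, C) * 90 / pi) %% 180 else NA_real_
  structure(list(mean_angle_deg = mean_deg, resultant_length = R,
                 n = length(sample$angles_deg), mean_defined = defined),
            class = "axial_summary")
}

#' @export
print.axial_summary <- function(x, ...) {
  cat(sprintf("<axial_summary> n = %d, mean angle = %s deg, R = %.4f\n",
              x$n,
              if (x$mean_defined) sprintf("%.2f", x$mean_angle_deg) else "NA",
              x$resultant_length))
  invisible(x)
}

#' Rao's spacing test of orientation uniformity
#'
#' Tests whether crack orientations are uniformly distributed (no
#' preferential orientation) against any form of angular bias. Because the
#' data are axial, angles are doubled onto the circle first (`axial = TRUE`,
#' the default). With sorted doubled angles and wrap-around spacings
#' \eqn{T_i}, the statistic is \eqn{U = \frac{1}{2}\sum_i |T_i - \lambda|}
#' with \eqn{\lambda = 360/n}; U = 0 iff the angles are exactly equally
#' spaced, and large U indicates clustering. U is compared against
#' Monte-Carlo-tabulated critical values (levels 0.10 / 0.05 / 0.01),
#' interpolated in n. Weights are ignored: the test sees each crack once.
#'
#' @param sample an [angle_sample()] with at least 4 angles.
#' @param alpha significance level, one of 0.10, 0.05, 0.01.
#' @param axial double the angles before testing (recommended for
#'   orientations); set FALSE to treat inputs as already-circular degrees.
#' @return A `rao_result` with `U_deg`, `n`, `alpha`, `critical_value_deg`,
#'   `significant`.
#' @export
rao_spacing_test <- function(sample, alpha = 0.05, axial = TRUE) {
  stopifnot(inherits(sample, "angle_sample"))
  n <- length(sample$angles_deg)
  if (n < 4L) {
    stop(sprintf("insufficient sample: Rao's spacing test needs n >= 4 (got %d)", n),
         call. = FALSE)
  }
  ang <- if (axial) (2 * sample$angles_deg) %% 360 else sample$angles_deg %% 360
  phi <- sort(ang)
  spacings <- c(diff(phi), 360 - phi[n] + phi[1])
  lambda <- 360 / n
  U <- 0.5 * sum(abs(spacings - lambda))
  crit <- rao_critical_value(n, alpha)
  structure(list(U_deg = U, n = n, alpha = alpha,
                 critical_value_deg = crit, significant = U > crit),
            class = "rao_result")
}

#' @export
print.rao_result <- function(x, ...) {
  cat(sprintf(
    "<rao_result> U = %.2f deg, n = %d, critical value (alpha = %.2f) = %.2f -> %s\n",
    x$U_deg, x$n, x$alpha, x$critical_value_deg,
    if (x$significant) "non-uniform (significant angular bias)"
    else "uniformity not rejected"))
  invisible(x)
}

#' Weighted axial polar histogram
#'
#' Bins orientations into equal-width half-open bins on `[0, 180)`. Bar
#' heights are the summed weights per bin (so sqrt-eigenvalue weighting
#' emphasises long cracks); raw unweighted counts are kept separately and
#' drive the bar colormap when plotted. For display the rose is mirrored to
#' `[180, 360)` so the axial symmetry is visible.
#'
#' @param sample an [angle_sample()].
#' @param n_bins number of bins over `[0, 180)` (default 18, i.e. 10-degree
#'   bins).
#' @return A `polar_histogram` with `breaks_deg` (length `n_bins + 1`),
#'   `heights` (summed weights) and `counts`.
#' @export
polar_histogram <- function(sample, n_bins = 18) {
  stopifnot(inherits(sample, "angle_sample"))
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  width <- 180 / n_bins
  bin <- pmin(floor(sample$angles_deg / width) + 1L, n_bins)
  heights <- vapply(seq_len(n_bins),
                    function(b) sum(sample$weights[bin == b]), numeric(1))
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(breaks_deg = seq(0, 180, by = width),
                 heights = heights, counts = counts, n_bins = n_bins),
            class = "polar_histogram")
}
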