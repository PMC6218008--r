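---
title: "Quantifying emerging cracks and cell separations: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying emerging cracks and cell separations: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cracksep)
```

## The problem

In a healthy plant epidermis stained for cell contours, cells form a
continuous sheet. In adhesion-defective mutants (the classic example is the
*Arabidopsis thaliana* `qua1-1` mutant imaged with propidium iodide),
neighbouring cells detach and the gap fills with a bright, closed patch of
signal — an emerging "crack". The same geometry appears in microcracks of
rocks and engineered materials. The number, size and orientation of such
cracks carry mechanical information: cracks tend to open perpendicular to
the direction of maximal tension, so an anisotropic, co-oriented crack
population is evidence of directional stress.

`cracksep` quantifies these cracks in preprocessed 2D 8-bit grayscale
images. It deliberately does *not* do the preprocessing: images are
expected to be already contrast-enhanced and median-smoothed, with a
per-image segmentation threshold chosen interactively and recorded as a
three-digit `_XXXthld` suffix in the filename. This keeps the one
judgement-dependent step (choosing the threshold) explicit and auditable,
and everything downstream deterministic.

## The pipeline

For each image the pipeline performs:

1. **Threshold segmentation.** `binarize()` marks pixels at least as bright
   as the threshold (`threshold_type = "min"`, bright cracks) or at most as
   dark (`"max"`). Comparisons are inclusive, matching the behaviour of the
   interactive threshold tool the workflow calibrates against.
2. **Component extraction.** `extract_regions()` labels connected
   components (4-connectivity by default, 8 configurable) and keeps those
   with area inside the inclusive `[min_area_of_crack, max_area_of_crack]`
   window. The lower bound removes speckle; the upper bound removes the
   background, which in a thresholded image is itself one huge component.
   Components are found on the pixel-adjacency graph and then relabelled
   `1..k` in raster-scan order of each component's first pixel, so labels —
   and therefore CSV outputs — are reproducible.
3. **Shape analysis.** For each crack, `principal_axes()` computes the
   centroid and the eigen-decomposition of the 2×2 covariance matrix of the
   pixel coordinates (population divisor N: a region is a complete pixel
   set, not a sample). The leading eigenvector gives the principal
   orientation; the eigenvalue pair gives the shape anisotropy
   \[(\lambda_1 - \lambda_2) / (\lambda_1 + \lambda_2)\],
   which is 0 for an isotropic blob, 1 for a perfect line, and invariant
   under rotation, translation and scaling. The alternative
   \(1 - \lambda_2/\lambda_1\) is available via
   `anisotropy_formula = "one_minus_ratio"` for comparison with other
   software.
4. **Axial circular statistics.** Orientations live on a half-circle
   (10° and 190° are the same crack axis), so all circular statistics use
   the standard axial correction: angles are doubled onto the full circle,
   the weighted mean resultant vector is computed there, and the mean
   direction is halved back to `[0°, 180°)`. The resultant length R is 1
   for perfectly co-oriented cracks and 0 for a homogeneous spread; when R
   is numerically zero the mean is undefined and reported as `NA`, never
   silently as 0.
5. **Uniformity test.** `rao_spacing_test()` applies Rao's spacing test to
   the doubled angles. Unlike the Rayleigh test it has power against
   multimodal departures (e.g. two orthogonal crack families). Per-crack
   weights are ignored here: the test sees each crack once.
6. **Series comparison.** Per-image *total* crack areas (µm²) of two
   series are compared by a data-driven test selection: Shapiro-Wilk
   normality on both series; any rejection routes to the two-sided Wilcoxon
   rank-sum test; otherwise Bartlett's variance test routes to Student's
   (pooled) or Welch's t test. Every intermediate p-value and the routing
   are recorded in the result so the decision can be re-derived.

## Conventions that matter

* **Angle convention.** Angles are measured counter-clockwise from the
  horizontal axis *as displayed* — image rows grow downward, so
  `angle = atan2(-dy_row, dx_col) mod 180`. A horizontal crack is 0°, a
  vertical one 90°, and a down-right diagonal on screen is 135°. Ties at
  180° map to 0°; the range is the half-open `[0°, 180°)`.
* **Degenerate regions.** A single pixel (or an exactly isotropic region)
  has a covariance eigenvalue tie; the eigenbasis is arbitrary, so the
  axis-aligned one is fixed by convention and the angle reported is 0°.
  Its anisotropy of 0 flags the angle as uninformative downstream.
* **Eigenvector sign.** Eigenvectors are reported with non-negative
  x-component (non-negative y when x is 0) so CSV output is deterministic.
* **Histogram weighting.** Polar histogram bars are weighted by the square
  root of each crack's principal eigenvalue — proportional to the crack's
  linear extent — while the bar *colour* encodes the raw, unweighted count
  per bin (yellow high, purple low). Summary statistics (per-image and
  pooled means, R, Rao test) use unit weights; the weighting is purely a
  display emphasis.
* **Overlay scaling.** In the vector-overlay figure each crack is drawn as
  a red cross along its eigenvectors with half-length
  \(2\sqrt{\lambda}\) — a pure display magnification, exposed in
  `vector_cross_segments()` so it can be verified numerically.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `pixel_size` | 1 µm | physical pixel edge; areas scale with its square |
| `min_area_of_crack` | 1 px | lower inclusive area bound (speckle filter) |
| `max_area_of_crack` | Inf px | upper inclusive area bound (background filter) |
| `threshold_type` | `"min"` | crack polarity (bright vs dark) |
| `connectivity` | 4 | component connectivity; 4 avoids merging cracks that touch only at corners |
| `n_bins` | 18 | 10° polar-histogram bins |
| `alpha` | 0.05 | level for the Shapiro/Bartlett gates and the Rao test |

The numeric threshold itself is never a global parameter: it is parsed per
image from the filename, which is what makes a mixed-quality dataset
analysable with one command.

## Numerical and statistical choices

* **Rao critical values.** The test is table-based (no asymptotic
  approximation). The critical-value table shipped in the package was
  tabulated by seeded Monte Carlo under the uniform null — 10⁶ replicates
  per sample size up to n = 50 and at least 3×10⁵ beyond, at levels
  0.10/0.05/0.01, for 39 sample sizes from 4 to 1000 — and agrees with the
  classical published tables to within ~0.1° where those report values.
  Lookups interpolate linearly in n; n > 1000 conservatively uses the
  n = 1000 row. The type-I error of the resulting test is itself verified
  by simulation in the test suite.
* **Exact vs approximate Wilcoxon.** The rank-sum test uses the exact
  distribution for tie-free samples up to n = 20 per group and the
  continuity-corrected normal approximation otherwise.
* **Undefined means.** R below 10⁻⁹ flags the circular mean as undefined
  (`NA` plus an explanatory note in the TXT summary).
* **Byte-identical reruns.** All CSV/TXT output is written with fixed
  6-significant-digit formatting and binary-mode connections, so two runs
  on identical input are bitwise identical — a property the test suite
  asserts end to end.

## The synthetic ground-truth generator

Real microscopy fixtures are bulky and have no pixel-level ground truth, so
validation uses `generate_crack_image()` / `generate_dataset()`: elliptical
cracks of known centre, semi-axes, orientation and intensity on a constant
background, with optional additive Gaussian noise (clipped to `[0, 255]`
and rounded). Ellipses are the canonical choice because their orientation
and anisotropy have closed forms, and the ground truth records the
*rasterized* pixel set's angle and anisotropy so recovery tests compare
like with like. Cracks must be pairwise non-adjacent under 8-connectivity,
mirroring the biological requirement that each separation be a closed
domain.

Default study conditions used across the tests: 64–128 px images,
background intensity 20, crack intensity ≈ 200–220 (an intensity gap well
above the threshold), noise σ of 0 (exact-recovery tests) to 10 (robustness
tests), 2–3 cracks per image with semi-axes roughly 8–20 × 2–5 px, and
2 series × 3 images for end-to-end runs. These sizes keep a full validation
run in seconds while exercising every code path; they were fixed once as
representative of the confocal images the method targets.

What the generator does *not* emulate: cell-wall texture, staining
gradients, uneven illumination, or cracks with concave outlines. Passing
the synthetic suite therefore demonstrates correctness of the measurement
chain, not robustness to every real-world artefact — on real data the
threshold choice remains the user's responsibility, and the protocol's own
advice applies: if cracks cannot be separated by a global per-image
threshold, this pipeline is not the right tool.

## Known limitations

* One threshold per image; no local/adaptive thresholding.
* Merged cracks are counted once (no watershed splitting).
* Orientation statistics assume consistently oriented images within a
  series; the pipeline reminds but does not register.
* With more than two series, all pairwise area comparisons are reported
  without multiple-testing correction (stated in the output file).
* The `updir/<series>/<image>_XXXthld.<ext>` layout is fixed; deeper
  nesting is not traversed.

## A minimal run

```{r example, eval = FALSE}
root <- file.path(tempdir(), "updir")
layout <- list(
  mutantA = list(img01 = scene_spec(
    96, 96, list(crack_spec(c(30, 30), 10, 3, 20, 220),
                 crack_spec(c(70, 60), 12, 4, 35, 220)),
    noise_sigma = 5, seed = 1)),
  mutantB = list(img01 = scene_spec(
    96, 96, list(crack_spec(c(40, 40), 8, 3, 120, 220)),
    noise_sigma = 5, seed = 2)))
generate_dataset(layout, thresholds = 110, root = root)

cfg <- run_config(updir = root, pixel_size = 0.5,
                  min_area_of_crack = 5, max_area_of_crack = 2000,
                  global_polarhist_output = TRUE)
bundle <- run_pipeline(cfg)
bundle$per_image
```
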