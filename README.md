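# cracksep

Detection and quantification of emerging cracks and cell-separation events
in 2D grayscale images.

In adhesion-defective plant mutants (e.g. *Arabidopsis thaliana* `qua1-1`
stained with propidium iodide), detached epidermal cells leave bright,
closed gaps — "cracks" — whose number, size and orientation reflect the
magnitude and direction of tissue tension. The same analysis applies to
microcracks in rocks and engineered materials. `cracksep` takes
preprocessed 8-bit images whose filenames encode a per-image segmentation
threshold (`sample_1_162thld.tif`), and produces per-crack shape
descriptors, per-series orientation statistics and cross-series area
comparisons.

## What it computes

For every crack (connected component above/below the threshold, filtered
by an inclusive pixel-area window), a principal component analysis of the
pixel coordinates gives:

- centroid, area in px and µm²;
- principal orientation θ ∈ [0°, 180°), from the leading eigenvector of
  the coordinate covariance matrix (population divisor N);
- shape anisotropy (λ₁ − λ₂)/(λ₁ + λ₂) ∈ [0, 1] — 0 for an isotropic
  blob, 1 for a perfect line;
- both eigenvalues and eigenvectors.

Orientations are axial (θ ≡ θ + 180°), so summaries use the doubled-angle
correction: the circular mean angle, the resultant vector length
R ∈ [0, 1] (1 = all cracks co-oriented, 0 = homogeneous spread), and Rao's
spacing test of orientation uniformity
U = ½ Σ|Tᵢ − 360°/n| on the sorted doubled-angle spacings Tᵢ, compared to
table-based critical values.

Per-image *total* crack areas of two sample series are compared by the
routed two-sample procedure: Shapiro-Wilk on both series → Wilcoxon
rank-sum if either rejects; otherwise Bartlett → Student's t (equal
variances) or Welch's t.

Outputs per image: a crack CSV, the inverted image, a label overlay, an
eigenvector-cross overlay and a polar orientation histogram (vector PDFs);
per series: a pooled polar histogram and a TXT summary; per comparison: a
boxplot and a TXT test report.

## Worked example

```r
library(cracksep)

# a small synthetic dataset: 2 series, elliptical cracks, noise sd 5
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
```

The per-crack CSV written next to the first image
(`img01_110thld_cracks.csv`) reads:

```
label,centroid_x,centroid_y,area_px,area_um2,angle_deg,anisotropy,lambda1,lambda2,v1_x,v1_y,v2_x,v2_y
1,30,30,97,24.25,19.2826,0.835071,25.7288,2.3124,0.943901,-0.330228,0.330228,0.943901
2,70,60,153,38.25,34.7724,0.789653,35.4772,4.16983,0.821424,-0.570318,0.570318,0.821424
```

Both cracks are recovered at their simulated positions; the nominal
orientations 20° and 35° come back as 19.3° and 34.8° (the small offset is
rasterization), areas are in µm² (pixel size 0.5 µm → 97 px = 24.25 µm²),
and the high anisotropies (0.84, 0.79) reflect the elongated ellipses. The
series summary TXT pools all cracks of a series:

```
Global analysis (all cracks of the series pooled):
  n_cracks = 4
  pooled mean_angle = 29.96
  pooled R = 0.959
  pooled mean_anisotropy = 0.804
  Rao spacing test: U = 227.55 deg, critical value = 186.51 deg (alpha = 0.05)
  decision: orientations are NOT uniform (significant angular bias)
```

A pooled R of 0.96 with a significant Rao test says these simulated cracks
share a strongly preferred axis — exactly what was generated.

A thin command-line wrapper with `run`, `simulate` and `inspect`
subcommands is installed at `inst/cli/cracksep.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cracksep.R", package="cracksep"))')" \
  run --updir updir --pixel_size 0.5 --min_area_of_crack 5 \
      --max_area_of_crack 2000 --global_polarhist_output
```

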