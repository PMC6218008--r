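Package: cracksep
Title: Detection and Quantification of Emerging Cracks and Cell-Separation
    Events in Grayscale Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-automatic pipeline for detecting and quantifying emerging
    cracks or cell-separation events in 2D 8-bit grayscale images, such as
    adhesion defects in plant epidermis or microcracks in materials.
    Segments contrasting regions by an intensity threshold encoded in each
    image filename, extracts connected components filtered by area, and
    characterises each crack by principal component analysis of its pixel
    coordinates (area, centroid, principal orientation, shape anisotropy,
    eigenpairs). Crack orientations are summarised with axial circular
    statistics (circular mean, resultant vector length, weighted polar
    histograms) and tested for uniformity with Rao's spacing test; per-image
    total crack areas of two sample series are compared through a
    normality- and variance-driven test-selection tree (Shapiro, Bartlett,
    Student, Welch, Wilcoxon rank sum). Includes a ground-truthed synthetic
    image generator for validation, and writes per-crack CSV tables,
    per-series text summaries and vector-PDF figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    igraph,
    jpeg,
    stats,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    jsonlite,
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
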