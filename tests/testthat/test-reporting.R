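make_descs <- function(n = 3) {
  set.seed(14)
  lapply(seq_len(n), function(i) {
    reg <- make_region(sample(5:40, 12, replace = TRUE) + i,
                       sample(5:40, 12, replace = TRUE))
    reg$pixels <- unique(reg$pixels); reg$area_px <- nrow(reg$pixels)
    reg$label <- i
    describe_crack(reg, pixel_size = 0.4)
  })
}

test_that("crack CSV writes one row per crack and round-trips at 6 digits", {
  dir <- withr::local_tempdir()
  descs <- make_descs(3)
  p <- file.path(dir, "cracks.csv")
  write_crack_csv(descs, p)
  expect_length(readLines(p), 4L)
  df <- read_crack_csv(p)
  expect_equal(nrow(df), 3L)
  expect_equal(names(df)[1:7],
               c("label", "centroid_x", "centroid_y", "area_px", "area_um2",
                 "angle_deg", "anisotropy"))
  for (i in seq_along(descs)) {
    d <- descs[[i]]
    rel <- function(a, b) abs(a - b) <= 1e-5 * max(abs(b), 1e-12)
    expect_true(rel(df$centroid_x[i], d$centroid[["x"]]))
    expect_true(rel(df$angle_deg[i], d$angle_deg))
    expect_true(rel(df$anisotropy[i], d$anisotropy))
    expect_true(rel(df$lambda1[i], d$eigenvalues[["lambda1"]]))
    expect_identical(df$area_px[i], d$area_px)
  }
  # degenerate: header-only file
  p0 <- file.path(dir, "empty.csv")
  write_crack_csv(list(), p0)
  expect_length(readLines(p0), 1L)
})

test_that("eigenvector cross half-lengths are 2 * sqrt(eigenvalue)", {
  d <- make_descs(1)[[1]]
  seg <- vector_cross_segments(d)
  expect_equal(seg$half_length,
               2 * sqrt(c(d$eigenvalues[["lambda1"]],
                          d$eigenvalues[["lambda2"]])))
  # geometric length of the drawn segment is twice the half-length
  len <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
  expect_equal(len, 2 * seg$half_length, tolerance = 1e-9)
  # explicit lambda = 9 -> half-length 6
  d$eigenvalues <- c(lambda1 = 9, lambda2 = 1)
  expect_equal(vector_cross_segments(d)$half_length, c(6, 2))
})

test_that("overlay figures render; the inverted image is 255 - intensity", {
  dir <- withr::local_tempdir()
  img <- intensity_image(matrix(100L, 40, 40))
  paths <- render_image_overlays(img, list(), list(),
                                 file.path(dir, "img"), format = "png")
  for (p in paths) expect_file_nonempty(p)
  inv <- png::readPNG(paths[1])
  expect_equal(unique(round(as.vector(inv[, , 1]) * 255)), 155)

  # with cracks: all three figures render as valid non-empty PDFs
  sc <- scene_spec(64, 64, list(crack_spec(c(32, 32), 10, 3, 30, 220)),
                   noise_sigma = 0)
  gen <- generate_crack_image(sc)
  regs <- segment_cracks(gen$image, segmentation_params(110, "min"))
  descs <- describe_cracks(regs)
  paths2 <- render_image_overlays(gen$image, descs, regs,
                                  file.path(dir, "crk"), format = "pdf")
  for (p in paths2) {
    expect_file_nonempty(p)
    expect_identical(readBin(p, "raw", 4), charToRaw("%PDF"))
  }
})

test_that("polar histogram renders for filled and empty samples", {
  dir <- withr::local_tempdir()
  h <- polar_histogram(angle_sample(c(10, 12, 100, 101, 102), 1:5))
  p1 <- file.path(dir, "rose.pdf")
  render_polar_histogram(h, p1)
  expect_file_nonempty(p1)
  p2 <- file.path(dir, "rose_empty.pdf")
  render_polar_histogram(NULL, p2)
  expect_file_nonempty(p2)
})

test_that("series summary lists every image then the pooled block", {
  dir <- withr::local_tempdir()
  per_image <- data.frame(
    image = c("a_100thld.tif", "b_100thld.tif"),
    n_cracks = c(3L, 4L),
    mean_angle_deg = c(41.2, NA),
    resultant_length = c(0.82, 0.0),
    mean_anisotropy = c(0.61, 0.55))
  pooled <- axial_mean_resultant(angle_sample(rep(30, 7)))
  rao <- rao_spacing_test(angle_sample(rep(30, 7)))
  p <- file.path(dir, "summary.txt")
  write_series_summary(per_image, pooled, rao, 0.58, p, "mutantA")
  txt <- readLines(p)
  expect_length(grep("^  [ab]_100thld", txt), 2L)
  expect_true(any(grepl("pooled R = 1.000", txt)))       # identical angles
  expect_true(any(grepl("NA \\(undefined", txt)))        # flagged mean
  expect_true(any(grepl("Rao spacing test", txt)))
  expect_true(any(grepl("NOT uniform", txt)))
})

test_that("comparison output enumerates all pairs and re-parses consistently", {
  dir <- withr::local_tempdir()
  set.seed(9)
  sl <- lapply(1:3, function(i)
    series_areas(paste0("ser", i), abs(rnorm(8, 50, 10))))
  res <- compare_all_series(sl)
  out <- render_comparison(res, sl, file.path(dir, "crack_area"))
  expect_file_nonempty(out[1])
  expect_file_nonempty(out[2])
  txt <- readLines(out[2])
  expect_length(grep(" vs ", txt), 3L)   # C(3,2) comparison blocks
  # the routing lines re-parse to the recorded choice
  chosen <- sub("  chosen test = ", "", grep("chosen test", txt, value = TRUE))
  expect_equal(chosen, vapply(res, `[[`, character(1), "chosen_test"))
})
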