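test_that("noise-free rasterization is recovered exactly by thresholding", {
  sc <- scene_spec(64, 64, list(crack_spec(c(32, 32), 10, 3, 0, 200)),
                   background_intensity = 20, noise_sigma = 0)
  gen <- generate_crack_image(sc)
  expect_s3_class(gen$image, "intensity_image")
  mask <- binarize(gen$image, 110, "min")
  got <- which(mask)
  want <- (gen$truth[[1]]$pixels[, "col"] - 1L) * 64 +
    gen$truth[[1]]$pixels[, "row"]
  expect_setequal(got, sort(want))
  expect_equal(gen$truth[[1]]$area_px, nrow(gen$truth[[1]]$pixels))
})

test_that("noise-free scenes are deterministic regardless of seed; noisy ones per seed", {
  mk <- function(sigma, seed) {
    scene_spec(48, 48, list(crack_spec(c(24, 24), 8, 3, 40, 210)),
               noise_sigma = sigma, seed = seed)
  }
  expect_identical(generate_crack_image(mk(0, 1))$image$pixels,
                   generate_crack_image(mk(0, 999))$image$pixels)
  n1 <- generate_crack_image(mk(10, 42))$image$pixels
  n2 <- generate_crack_image(mk(10, 42))$image$pixels
  n3 <- generate_crack_image(mk(10, 43))$image$pixels
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1)
  invisible(generate_crack_image(
    scene_spec(32, 32, list(crack_spec(c(16, 16), 5, 2, 10, 200)),
               noise_sigma = 5, seed = 7)))
  expect_identical(runif(1), before)
})

test_that("overlapping or touching cracks are rejected", {
  expect_error(generate_crack_image(
    scene_spec(64, 64, list(crack_spec(c(30, 30), 10, 4, 0, 200),
                            crack_spec(c(34, 30), 10, 4, 0, 200)))),
    "overlap|touch")
  expect_error(generate_crack_image(
    scene_spec(64, 64, list(crack_spec(c(20, 30), 6, 2, 0, 200),
                            crack_spec(c(33, 30), 6, 2, 0, 200)))),
    "touch|overlap")
})

test_that("generate_dataset round-trips through scan_dataset", {
  root <- file.path(withr::local_tempdir(), "updir")
  written <- generate_dataset(demo_layout(), thresholds = 110, root = root)
  expect_equal(nrow(written), 4L)
  expect_length(list.files(root, pattern = "\\.tif$", recursive = TRUE), 4L)
  expect_length(list.files(root, pattern = "_truth\\.csv$", recursive = TRUE),
                4L)
  idx <- suppressWarnings(scan_dataset(root))
  expect_named(idx$series, c("mutantA", "mutantB"))
  expect_equal(unname(vapply(idx$series, nrow, 1L)), c(2L, 2L))
  expect_true(all(unlist(lapply(idx$series, `[[`, "threshold")) == 110L))

  # refuses to clobber unless asked
  expect_error(generate_dataset(demo_layout(), 110, root), "refusing")
  expect_silent(generate_dataset(demo_layout(), 110, root, overwrite = TRUE))

  expect_error(generate_dataset(list(), 110, withr::local_tempdir()), "empty")
  expect_error(generate_dataset(demo_layout(), 1000,
                                file.path(withr::local_tempdir(), "x")),
               "\\[0, 999\\]")
})

test_that("end-to-end recovery on noise-free scenes is exact", {
  set.seed(60)
  for (rep in 1:10) {
    ang1 <- runif(1, 0, 180); ang2 <- runif(1, 0, 180)
    sc <- scene_spec(96, 96,
                     list(crack_spec(c(28, 28), 12, 3, ang1, 220),
                          crack_spec(c(68, 66), 14, 4, ang2, 220)),
                     background_intensity = 20, noise_sigma = 0)
    gen <- generate_crack_image(sc)
    regs <- segment_cracks(gen$image,
                           segmentation_params(120, "min",
                                               min_area_px = 2,
                                               max_area_px = 2000))
    expect_length(regs, 2L)
    areas_got <- sort(vapply(regs, `[[`, 1L, "area_px"))
    areas_want <- sort(vapply(gen$truth, `[[`, 1L, "area_px"))
    expect_identical(areas_got, areas_want)
    for (r in regs) {
      d <- describe_crack(r)
      tr <- gen$truth[[which.min(vapply(gen$truth, function(t)
        sum((colMeans(t$pixels) - colMeans(r$pixels))^2), numeric(1)))]]
      if (tr$anisotropy > 0.5) {
        diff <- abs(d$angle_deg - tr$angle_deg)
        expect_lte(min(diff, 180 - diff), 2)
      }
      expect_lte(abs(d$anisotropy - tr$anisotropy), 0.05)
    }
  }
})

test_that("crack counts survive moderate noise when the contrast gap is wide", {
  recovered <- 0L; total <- 0L
  for (seed in 1:20) {
    sc <- scene_spec(96, 96,
                     list(crack_spec(c(28, 28), 12, 3, 35, 200),
                          crack_spec(c(68, 66), 14, 4, 120, 200)),
                     background_intensity = 20, noise_sigma = 10, seed = seed)
    gen <- generate_crack_image(sc)
    regs <- segment_cracks(gen$image,
                           segmentation_params(110, "min",
                                               min_area_px = 10,
                                               max_area_px = 2000))
    recovered <- recovered + length(regs)
    total <- total + length(gen$truth)
  }
  expect_gte(recovered / total, 0.95)
})
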