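test_that("principal axes match hand-computed covariance eigenpairs", {
  # single pixel at (row 5, col 7): zero covariance, axis-aligned convention
  pa1 <- principal_axes(make_region(5, 7))
  expect_equal(pa1$centroid, c(x = 7, y = 5))
  expect_equal(unname(pa1$eigenvalues), c(0, 0))
  expect_equal(unname(pa1$eigenvectors[, "v1"]), c(1, 0))

  # horizontal run of 5 pixels: population variance of {0..4} = 2
  pa2 <- principal_axes(make_region(rep(3, 5), 0:4 + 1))
  expect_equal(unname(pa2$eigenvalues), c(2, 0))
  expect_equal(unname(pa2$eigenvectors[, "v1"]), c(1, 0))

  # diagonal (row,col) = (0,0),(1,1),(2,2): oracle by direct covariance
  pix <- cbind(x = c(0, 1, 2), y = c(0, 1, 2))
  covm <- crossprod(sweep(pix, 2, colMeans(pix))) / 3
  ref <- eigen(covm, symmetric = TRUE)
  pa3 <- principal_axes(make_region(c(0, 1, 2) + 1, c(0, 1, 2) + 1))
  expect_equal(unname(pa3$eigenvalues), ref$values, tolerance = 1e-12)
  expect_equal(pa3$eigenvalues[["lambda2"]], 0, tolerance = 1e-12)
  # down-right screen diagonal -> 135 degrees under the screen convention
  expect_equal(principal_angle(pa3$eigenvectors[, "v1"]), 135)
})

test_that("eigenvectors are orthonormal with the fixed sign convention", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:60, 1)
    reg <- make_region(sample(1:30, n, replace = TRUE),
                       sample(1:30, n, replace = TRUE))
    reg$pixels <- unique(reg$pixels); reg$area_px <- nrow(reg$pixels)
    pa <- principal_axes(reg)
    v <- pa$eigenvectors
    expect_equal(crossprod(v), diag(2), tolerance = 1e-9, ignore_attr = TRUE)
    expect_gte(v["x", "v1"], 0)
    expect_gte(pa$eigenvalues[["lambda1"]], pa$eigenvalues[["lambda2"]])
    expect_gte(pa$eigenvalues[["lambda2"]], 0)
    # lambda1 + lambda2 equals the covariance trace
    xy <- cbind(reg$pixels[, "col"], reg$pixels[, "row"])
    tr <- sum(diag(crossprod(sweep(xy, 2, colMeans(xy))) / nrow(xy)))
    expect_equal(sum(pa$eigenvalues), tr, tolerance = 1e-9)
  }
})

test_that("principal angle follows the screen convention on [0, 180)", {
  expect_equal(principal_angle(c(1, 0)), 0)    # horizontal
  expect_equal(principal_angle(c(0, 1)), 90)   # vertical (rows grow down)
  expect_equal(principal_angle(c(1, 1)), 135)  # down-right on screen
  expect_equal(principal_angle(c(1, -1)), 45)  # up-right on screen
  set.seed(8)
  for (th in runif(50, -pi, pi)) {
    a <- principal_angle(c(cos(th), sin(th)))
    expect_gte(a, 0); expect_lt(a, 180)
  }
})

test_that("shape anisotropy formulas and contract", {
  expect_equal(shape_anisotropy(4, 4), 0)
  expect_equal(shape_anisotropy(2, 0), 1)
  expect_equal(shape_anisotropy(3, 1), 0.5)
  expect_equal(shape_anisotropy(0, 0), 0)
  expect_equal(shape_anisotropy(3, 1, formula = "one_minus_ratio"), 2 / 3)
  expect_error(shape_anisotropy(1, 2), "contract violation")
  expect_error(shape_anisotropy(1, -0.5), "contract violation")
})

test_that("describe_crack assembles areas and conventions", {
  reg <- make_region(rep(1:10, each = 10), rep(1:10, times = 10))
  d <- describe_crack(reg, pixel_size = 0.5)
  expect_equal(d$area_px, 100L)
  expect_equal(d$area_um2, 25)
  d1 <- describe_crack(make_region(4, 4), pixel_size = 1)
  expect_equal(d1$area_um2, 1)
  expect_equal(d1$anisotropy, 0)
  expect_equal(d1$angle_deg, 0)
})

test_that("rasterized ellipses recover orientation and anisotropy", {
  for (ang in c(0, 30, 60, 90, 120, 150)) {
    sc <- scene_spec(96, 96,
                     list(crack_spec(c(48, 48), 20, 5, ang, 200)),
                     background_intensity = 20, noise_sigma = 0)
    gen <- generate_crack_image(sc)
    regs <- segment_cracks(gen$image, segmentation_params(110, "min"))
    expect_length(regs, 1L)
    d <- describe_crack(regs[[1]])
    diff <- abs(d$angle_deg - ang)
    expect_lte(min(diff, 180 - diff), 2)
    expect_gt(d$anisotropy, 0.6)
    expect_lte(abs(d$anisotropy - gen$truth[[1]]$anisotropy), 0.05)
  }
})

test_that("descriptors are translation invariant except the centroid", {
  rows <- c(2, 2, 3, 3, 4, 5); cols <- c(4, 5, 4, 6, 6, 7)
  a <- describe_crack(make_region(rows, cols))
  b <- describe_crack(make_region(rows + 9, cols + 4))
  expect_equal(b$centroid, a$centroid + c(x = 4, y = 9))
  expect_identical(b$area_px, a$area_px)
  expect_equal(b$angle_deg, a$angle_deg)
  expect_equal(b$anisotropy, a$anisotropy)
  expect_equal(b$eigenvalues, a$eigenvalues)
})

test_that("anisotropy is scale invariant; eigenvalues scale as s^2", {
  rows <- c(1, 1, 2, 3, 3, 4); cols <- c(1, 2, 2, 3, 4, 4)
  a <- principal_axes(make_region(rows, cols))
  s <- 3
  b <- principal_axes(make_region(rows * s, cols * s))
  expect_equal(unname(b$eigenvalues), unname(a$eigenvalues) * s^2,
               tolerance = 1e-12)
  expect_equal(shape_anisotropy(b$eigenvalues[[1]], b$eigenvalues[[2]]),
               shape_anisotropy(a$eigenvalues[[1]], a$eigenvalues[[2]]),
               tolerance = 1e-12)
})

test_that("rotating a synthetic crack rotates its angle, anisotropy stable", {
  base <- 25
  d0 <- local({
    sc <- scene_spec(96, 96, list(crack_spec(c(48, 48), 18, 4, base, 200)),
                     noise_sigma = 0)
    gen <- generate_crack_image(sc)
    describe_crack(segment_cracks(gen$image,
                                  segmentation_params(110, "min"))[[1]])
  })
  for (delta in c(40, 90, 130)) {
    d1 <- local({
      sc <- scene_spec(96, 96,
                       list(crack_spec(c(48, 48), 18, 4,
                                       (base + delta) %% 180, 200)),
                       noise_sigma = 0)
      gen <- generate_crack_image(sc)
      describe_crack(segment_cracks(gen$image,
                                    segmentation_params(110, "min"))[[1]])
    })
    shift <- abs((d1$angle_deg - d0$angle_deg) %% 180 - delta %% 180)
    expect_lte(min(shift, 180 - shift), 2)
    expect_lte(abs(d1$anisotropy - d0$anisotropy), 0.05)
  }
})
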