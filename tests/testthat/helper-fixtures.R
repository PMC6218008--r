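# shared fixtures: hand-built regions, brute-force labeling oracle, and
# small synthetic dataset trees

make_region <- function(rows, cols, label = 1L) {
  structure(list(label = label,
                 pixels = cbind(row = as.integer(rows), col = as.integer(cols)),
                 area_px = length(rows)),
            class = "crack_region")
}

# independent oracle: breadth-first flood fill, one component at a time
brute_label <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand.grid(dr = -1:1, dc = -1:1) |>
      (\(g) lapply(seq_len(nrow(g)), function(i) c(g$dr[i], g$dc[i])))() |>
      Filter(f = function(o) any(o != 0))
  }
  k <- 0L  # raster scan: top row first, left to right
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    k <- k + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- k
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        r <- p[1] + o[1]; cc <- p[2] + o[2]
        if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
            mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- k
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# a small two-series noise-free dataset layout used by io/pipeline tests
demo_layout <- function(noise_sigma = 0, seed = 1L, n_images = 2L) {
  scene_at <- function(angle, seed) {
    scene_spec(96, 96,
               list(crack_spec(c(30, 30), 10, 3, angle, 220),
                    crack_spec(c(70, 65), 12, 4, (angle + 50) %% 180, 220)),
               background_intensity = 20, noise_sigma = noise_sigma,
               seed = seed)
  }
  series <- function(base_angle, base_seed) {
    scenes <- lapply(seq_len(n_images), function(i) {
      scene_at((base_angle + 15 * i) %% 180, base_seed + i)
    })
    names(scenes) <- sprintf("img%02d", seq_len(n_images))
    scenes
  }
  list(mutantA = series(10, seed), mutantB = series(95, seed + 100L))
}

expect_file_nonempty <- function(path) {
  expect_true(file.exists(path), info = path)
  expect_gt(file.info(path)$size, 0)
}
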