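test_that("distance transform agrees with brute force on anisotropic grids", {
  set.seed(7)
  d <- c(9, 7, 5)
  occ <- array(runif(prod(d)) < 0.55, dim = d)
  sp <- c(0.4, 0.7, 1.3)
  v <- voxel_volume(occ, sp)
  edt <- distance_transform(v)
  idx <- which(occ, arr.ind = TRUE)
  bg <- which(!occ, arr.ind = TRUE)
  for (k in sample(nrow(idx), min(25, nrow(idx)))) {
    p <- (idx[k, ] - 1) * sp
    brute <- min(sqrt(colSums((t(bg - 1) * sp - p)^2)))
    expect_equal(edt[idx[k, 1], idx[k, 2], idx[k, 3]], brute,
                 tolerance = 1e-10)
  }
  expect_true(all(edt[!occ] == 0))
})

test_that("inscribed diameter recovers a sphere's diameter", {
  bp <- single_cylinder_blueprint(10, 5)
  bp$x1 <- bp$x0; bp$y1 <- bp$y0; bp$z1 <- bp$z0; bp$length <- 0
  v <- rasterize(bp, c(1, 1, 1))
  ctr <- c(bp$x0, bp$y0, bp$z0)
  expect_equal(inscribed_diameter(v, ctr), 20, tolerance = 1 / 20 + 1e-9)

  # a foreground voxel touching background is at most two pitches thick
  idx <- which(v$occ, arr.ind = TRUE)
  surf <- idx[which.max(abs(idx[, 1] - mean(idx[, 1]))), ]
  p_surf <- (surf - 1) * v$spacing + v$origin
  expect_lte(inscribed_diameter(v, p_surf), 2 * max(v$spacing) + 1e-9)

  # origin shift leaves the result unchanged
  v2 <- voxel_volume(v$occ, v$spacing, v$origin + c(5, -3, 2))
  expect_equal(inscribed_diameter(v2, ctr + c(5, -3, 2)),
               inscribed_diameter(v, ctr))

  expect_error(inscribed_diameter(v, ctr + c(50, 0, 0)), "outside")
  bgpt <- v$origin # padded corner is background
  expect_error(inscribed_diameter(v, bgpt), "background")
})

test_that("volumes round-trip through TIFF stacks with spacing sidecar", {
  bp <- y_blueprint()
  v <- rasterize(bp, c(0.5, 0.5, 1.5))
  dir <- file.path(tempdir(), "vol_tiff")
  write_volume_tiff(v, dir)
  v2 <- read_volume_tiff(dir)
  expect_identical(v2$occ, v$occ)
  expect_equal(v2$spacing, v$spacing)
  expect_equal(v2$origin, v$origin)
})

test_that("largest component filtering drops disconnected debris", {
  occ <- array(FALSE, c(10, 10, 10))
  occ[2:6, 2:6, 2:6] <- TRUE
  occ[9, 9, 9] <- TRUE
  v <- largest_component(voxel_volume(occ, c(1, 1, 1)))
  expect_equal(sum(v$occ), 125)
  expect_false(v$occ[9, 9, 9])
})
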