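test_that("branch measures recover constructed geometry", {
  bp <- y_blueprint(angle = 60)
  sk <- skeletonize(rasterize(bp, c(0.33, 0.33, 1.5)))
  m <- measure_branches(sk)
  tips <- m[m$is_tip, ]
  expect_equal(nrow(tips), 2)
  # both children deflected 30 degrees: sibling angle 60, growth angle 30
  expect_equal(tips$b_angle, c(60, 60), tolerance = 10 / 60)
  expect_equal(tips$g_angle, c(30, 30), tolerance = 8 / 30)
  expect_true(all(m$rb >= 0))
  expect_true(all(m$b_angle >= 0 & m$b_angle <= 180, na.rm = TRUE))
  expect_true(all(m$g_angle >= 0 & m$g_angle <= 180))
})

test_that("a vertical cylinder has a growth angle near zero", {
  sk <- skeletonize(rasterize(single_cylinder_blueprint(3, 40), c(1, 1, 1)))
  m <- measure_branches(sk)
  expect_lt(m$g_angle, 5)
})

test_that("branch spacing matches the blueprint for parallel branches", {
  # short trunk splitting into two parallel vertical branches 12 mm apart
  bp <- y_blueprint()
  seg <- function(id, parent, gen, a, b, r) {
    data.frame(id = id, parent = parent, generation = gen,
               x0 = a[1], y0 = a[2], z0 = a[3],
               x1 = b[1], y1 = b[2], z1 = b[3],
               radius = r, length = sqrt(sum((b - a)^2)),
               b_angle_true = NA_real_, g_angle_true = NA_real_)
  }
  custom <- rbind(seg(1L, 0L, 1L, c(0, 0, 0), c(0, 8, 0), 2),
                  seg(2L, 1L, 2L, c(0, 8, 0), c(-6, 48, 0), 2),
                  seg(3L, 1L, 2L, c(0, 8, 0), c(6, 48, 0), 2))
  for (at in c("species_label", "growth_axis", "params", "seed")) {
    attr(custom, at) <- attr(bp, at)
  }
  class(custom) <- class(bp)
  # geometry: tips level at y = 48, centerlines 12 mm apart at the top
  truth <- blueprint_truth(custom)
  sk <- skeletonize(rasterize(custom, c(0.33, 0.33, 1.5)))
  m <- measure_branches(sk)
  got <- sort(m$br_spacing[m$is_tip])
  want <- sort(unname(truth$tip_spacing))
  expect_equal(length(got), length(want))
  expect_equal(got, want, tolerance = 1.5 / min(want))
})

test_that("aggregation computes the three colony traits", {
  meas <- data.frame(branch = 1L, is_tip = TRUE, da = 4, db = 4, dc = 4,
                     b_angle = NA, g_angle = 0, rb = 20, br_spacing = 7,
                     diameter = 4, n_points = 30L)
  f <- aggregate_features(meas, "c")
  expect_equal(f$length_thickness_ratio, 5)
  expect_equal(f$thickness, 4)
  expect_equal(f$spacing, 7)

  many <- meas[rep(1, 5), ]
  many$branch <- 1:5
  expect_equal(aggregate_features(many, "c")[, -1], f[, -1])

  no_tip <- meas
  no_tip$is_tip <- FALSE
  no_tip$br_spacing <- NA
  expect_error(aggregate_features(no_tip, "c"), "spacing")
})

test_that("trait normalization standardizes columns (sample sd)", {
  feats <- data.frame(colony_id = c("a", "b"), thickness = c(2, 4),
                      spacing = c(10, 6), length_thickness_ratio = c(5, 5.5))
  fm <- normalize_features(feats)
  # two colonies under the n-1 convention standardize to +/- 1/sqrt(2)
  expect_equal(abs(unname(fm)),
               matrix(1 / sqrt(2), 2, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(colMeans(fm), c(thickness = 0, spacing = 0,
                               length_thickness_ratio = 0),
               tolerance = 1e-12)

  same <- data.frame(colony_id = c("a", "b", "c"), t1 = c(1, 1, 1),
                     t2 = c(0, 1, 2))
  expect_warning(fm2 <- normalize_features(same), "zero variance")
  expect_true(all(fm2[, "t1"] == 0))
  expect_error(normalize_features(feats[1, ]), "2 colonies")
})

test_that("morphological distances are Euclidean over traits", {
  fm <- rbind(a = c(0, 0, 0), b = c(3, 4, 0))
  d <- morphological_distances(fm)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "a"], 0)

  set.seed(42)
  fm20 <- matrix(rnorm(60), 20, 3,
                 dimnames = list(paste0("c", 1:20), NULL))
  d20 <- morphological_distances(fm20)
  for (i in 1:19) {
    for (j in (i + 1):20) {
      expect_equal(d20[i, j], sqrt(sum((fm20[i, ] - fm20[j, ])^2)),
                   tolerance = 1e-12)
    }
  }
  fm_bad <- fm
  fm_bad[1, 1] <- NaN
  expect_error(morphological_distances(fm_bad), "NaN")
})

test_that("rotating a colony about the growth axis barely changes traits", {
  bp <- generate_colony_blueprint(list(mean_radius = 2.5,
                                       mean_branch_length = 22,
                                       branch_angle = 65,
                                       n_generations = 3),
                                  seed = 12, angle_jitter_sd = 3,
                                  length_cv = 0.05, radius_cv = 0.03)
  rot <- bp
  rot[, c("x0", "z0")] <- cbind(-bp$z0, bp$x0)
  rot[, c("x1", "z1")] <- cbind(-bp$z1, bp$x1)
  feats <- lapply(list(bp, rot), function(b) {
    sk <- suppressWarnings(skeletonize(rasterize(b, c(0.33, 0.33, 1.5))))
    aggregate_features(measure_branches(sk), "c")
  })
  expect_equal(feats[[1]]$thickness, feats[[2]]$thickness, tolerance = 0.05)
  expect_equal(feats[[1]]$spacing, feats[[2]]$spacing, tolerance = 0.05)
})

test_that("scaling a blueprint scales traits and preserves the ratio", {
  base <- generate_colony_blueprint(list(mean_radius = 2,
                                         mean_branch_length = 18,
                                         branch_angle = 70,
                                         n_generations = 2),
                                    seed = 5)
  scaled <- base
  k <- 1.5
  for (cl in c("x0", "y0", "z0", "x1", "y1", "z1", "radius", "length")) {
    scaled[[cl]] <- base[[cl]] * k
  }
  f1 <- aggregate_features(measure_branches(
    skeletonize(rasterize(base, c(0.33, 0.33, 1.5)))), "a")
  f2 <- aggregate_features(measure_branches(
    skeletonize(rasterize(scaled, c(0.33, 0.33, 1.5)))), "b")
  expect_equal(f2$thickness / f1$thickness, k, tolerance = 0.1)
  expect_equal(f2$spacing / f1$spacing, k, tolerance = 0.1)
  expect_equal(f2$length_thickness_ratio, f1$length_thickness_ratio,
               tolerance = 0.12)
})
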