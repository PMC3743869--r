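test_that("blueprint base cases and determinism", {
  bp1 <- single_cylinder_blueprint(3, 40)
  expect_equal(nrow(bp1), 1)
  expect_equal(blueprint_truth(bp1)$n_bifurcations, 0)

  bp2 <- y_blueprint(angle = 45)
  expect_equal(bp2$b_angle_true[-1], c(45, 45))

  a <- generate_colony_blueprint(list(mean_radius = 2, mean_branch_length = 20,
                                      branch_angle = 50, n_generations = 3),
                                 seed = 9, angle_jitter_sd = 5,
                                 length_cv = 0.1, radius_cv = 0.05)
  b <- generate_colony_blueprint(list(mean_radius = 2, mean_branch_length = 20,
                                      branch_angle = 50, n_generations = 3),
                                 seed = 9, angle_jitter_sd = 5,
                                 length_cv = 0.1, radius_cv = 0.05)
  expect_identical(as.data.frame(a), as.data.frame(b))

  expect_error(generate_colony_blueprint(
    list(mean_radius = -1, mean_branch_length = 10, branch_angle = 45,
         n_generations = 2), seed = 1), "positive")
  # nearly parallel fat siblings overlap along their whole length
  expect_error(generate_colony_blueprint(
    list(mean_radius = 5, mean_branch_length = 30, branch_angle = 4,
         n_generations = 3), seed = 1), "degenerate")
})

test_that("rasterized sphere volume matches the lattice-count oracle", {
  bp <- single_cylinder_blueprint(10, 5)
  bp$x1 <- bp$x0; bp$y1 <- bp$y0; bp$z1 <- bp$z0; bp$length <- 0
  v <- rasterize(bp, c(1, 1, 1))
  # oracle: brute-force count of lattice points within radius 10 of a center
  # on the same offset grid as the rasterizer
  ctr <- c(bp$x0, bp$y0, bp$z0)
  g <- expand.grid(x = seq(ctr[1] - 12, ctr[1] + 12, by = 1) + 0.5,
                   y = seq(ctr[2] - 12, ctr[2] + 12, by = 1) + 0.5,
                   z = seq(ctr[3] - 12, ctr[3] + 12, by = 1) + 0.5)
  oracle <- sum((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <= 100)
  expect_equal(sum(v$occ), oracle, tolerance = 0.02)
  expect_equal(sum(v$occ), 4 / 3 * pi * 1000, tolerance = 0.05)
})

test_that("rasterization respects crop boxes and spacing", {
  bp <- single_cylinder_blueprint(2, 20)
  expect_error(rasterize(bp, c(1, 1, 1),
                         crop = list(min = c(100, 100, 100),
                                     max = c(110, 110, 110))),
               "outside")
  v1 <- rasterize(bp, c(0.5, 0.5, 0.5))
  v2 <- rasterize(bp, c(1, 1, 1))
  ext1 <- apply(which(v1$occ, arr.ind = TRUE), 2, function(i) diff(range(i)))
  ext2 <- apply(which(v2$occ, arr.ind = TRUE), 2, function(i) diff(range(i)))
  expect_equal(as.numeric(ext1), as.numeric(2 * ext2), tolerance = 0.15)
})

test_that("genotype simulation honours its degenerate parameters", {
  s0 <- simulate_genotypes(3, 2, seq_length = 100, divergence = 0,
                           within_divergence = 0, heterozygosity = 0.5,
                           seed = 4)
  gd <- genetic_distance_matrix(s0$genotypes)
  expect_true(all(gd == 0))

  s1 <- simulate_genotypes(4, 2, seq_length = 100, divergence = 0.05,
                           heterozygosity = 0, seed = 4)
  expect_true(all(vapply(s1$genotypes, function(g) length(g$alleles), 0L) == 1))

  expect_error(simulate_genotypes(3, 1, hybrid_samples = 1, seed = 1),
               "2 species")
  expect_error(simulate_genotypes(3, 2, seq_length = 10, seed = 1), ">= 50")

  hy <- simulate_genotypes(3, 3, seq_length = 100, divergence = 0.2,
                           heterozygosity = 0, hybrid_samples = 2, seed = 5)
  expect_length(hy$hybrids, 2)
  hg <- hy$genotypes[[match(hy$hybrids[1],
                            vapply(hy$genotypes, `[[`, "", "sample_id"))]]
  expect_length(hg$alleles, 2)
})

test_that("observed p-distances match the substitution model expectation", {
  s <- simulate_genotypes(2, 3, seq_length = 10000, divergence = 0.1,
                          heterozygosity = 0, seed = 11)
  gd <- genetic_distance_matrix(s$genotypes)
  sp <- s$species[rownames(gd)]
  between <- unclass(gd)[outer(sp, sp, `!=`) & upper.tri(gd)]
  expected <- expected_p_distance(0.1 + 0.01) # species path + allele depths
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(mean(between) - expected), 3 * se)
  within <- unclass(gd)[outer(sp, sp, `==`) & upper.tri(gd)]
  expect_lt(mean(within), mean(between))
})

test_that("congruent datasets are deterministic and labelled consistently", {
  a <- generate_congruent_dataset(3, 12, seed = 21)
  b <- generate_congruent_dataset(3, 12, seed = 21)
  expect_identical(a$features, b$features)
  expect_identical(unclass(a$genetic_dist), unclass(b$genetic_dist))
  expect_identical(rownames(a$features), rownames(a$genetic_dist))
  expect_identical(rownames(a$morph_dist), rownames(a$genetic_dist))
  c2 <- generate_congruent_dataset(3, 12, seed = 22)
  expect_false(identical(a$features, c2$features))
  expect_error(generate_congruent_dataset(-1, 12, seed = 1), ">= 0")
  expect_error(generate_congruent_dataset(1, 3, seed = 1), "4 samples")
})

test_that("strong trait separation yields detectable congruence", {
  d <- generate_congruent_dataset(6, 15, seed = 31)
  mt <- mantel_test(d$morph_dist, d$genetic_dist, n_perm = 199, seed = 1)
  expect_lt(mt$p, 0.05)
})
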