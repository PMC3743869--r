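test_that("Mantel statistics behave on identity and affine inputs", {
  d1 <- random_dist(8, 1)
  r_self <- mantel_test(d1, d1, n_perm = 99, seed = 1)
  expect_equal(r_self$r, 1)
  expect_equal(r_self$p, 1 / 100) # minimum attainable with 99 permutations

  aff <- unclass(d1) * 2 + 3
  diag(aff) <- 0
  r_aff <- mantel_test(d1, dist_matrix(aff), n_perm = 99, seed = 1)
  expect_equal(r_aff$r, 1)
  expect_false(isTRUE(all.equal(r_aff$Z, r_self$Z))) # Z is not affine-invariant

  const <- matrix(1, 8, 8, dimnames = dimnames(d1))
  diag(const) <- 0
  expect_error(mantel_test(d1, dist_matrix(const), n_perm = 9, seed = 1),
               "d2.*constant|constant.*d2")
  expect_error(mantel_test(d1, d1, n_perm = 0, seed = 1), "n_perm")
  expect_error(mantel_test(random_dist(3, 1), random_dist(3, 1),
                           n_perm = 9, seed = 1), "4 objects")
  d2 <- random_dist(8, 2)
  rownames(d2) <- colnames(d2) <- paste0("z", 1:8)
  expect_error(mantel_test(d1, d2, n_perm = 9, seed = 1), "same labels")
})

test_that("Mantel r agrees with an independent implementation", {
  d1 <- random_dist(12, 5)
  d2 <- random_dist(12, 6)
  mine <- mantel_test(d1, d2, n_perm = 199, seed = 3)
  ref <- vegan::mantel(stats::as.dist(unclass(d1)),
                       stats::as.dist(unclass(d2)), permutations = 199)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("Kendall's W handles ties and matches the m=2 identity", {
  expect_equal(kendall_w(rbind(1:6, 1:6)), 1)
  expect_equal(kendall_w(rbind(1:6, 6:1)), 0)
  expect_error(kendall_w(rbind(rep(1, 5), 1:5)), "constant")
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(5:20, 1)
    tied <- rep %% 2 == 0
    a <- if (tied) rank(sample(1:5, n, TRUE), ties.method = "average")
         else sample(n)
    b <- if (tied) rank(sample(1:6, n, TRUE), ties.method = "average")
         else sample(n)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    W <- kendall_w(rbind(a, b))
    rho <- stats::cor(a, b) # Pearson on mid-ranks = Spearman with ties
    # exact for tie-free rankings; unequal tie structure shifts the
    # normalization slightly (arithmetic vs geometric mean of variances)
    expect_equal(W, (1 + rho) / 2, tolerance = if (tied) 2e-3 else 1e-12)
  }
})

test_that("CADM reports W, global p and a posteriori correlations", {
  d <- random_dist(9, 11)
  res <- cadm_test(list(d, d, d), n_perm = 99, seed = 2)
  expect_equal(res$W, 1)
  expect_equal(res$p_global, 1 / 100)
  expect_equal(res$posthoc$r, rep(1, 3))

  d2 <- random_dist(9, 12)
  two <- cadm_test(list(a = d, b = d2), n_perm = 199, seed = 5)
  expect_equal(two$W, (1 + two$posthoc$r[1]) / 2, tolerance = 1e-12)
  expect_equal(two$posthoc$r[1], two$posthoc$r[2], tolerance = 1e-12)

  ref <- suppressWarnings(ape::CADM.global(rbind(unclass(d), unclass(d2)),
                                           2, 9, nperm = 9))
  expect_equal(two$W, unname(ref$congruence_analysis["W", 1]),
               tolerance = 1e-10)
})

test_that("the m=2 identity holds on tied and untied inputs", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    d1 <- random_dist(n, 300 + rep)
    tied <- rep %% 2 == 0
    d2 <- if (tied) {
      # force ties by rounding
      dist_matrix(round(unclass(random_dist(n, 600 + rep)), 1))
    } else {
      random_dist(n, 600 + rep)
    }
    res <- cadm_test(list(d1, d2), n_perm = 19, seed = rep)
    # exact without ties; with unequal tie structure the two normalizations
    # (arithmetic vs geometric mean of rank variances) differ slightly
    expect_equal(res$W, (1 + res$posthoc$r[1]) / 2,
                 tolerance = if (tied) 1e-3 else 1e-12)
  }
})

test_that("permutation p-values follow the add-one convention", {
  d1 <- random_dist(10, 21)
  d2 <- random_dist(10, 22)
  mt <- mantel_test(d1, d2, n_perm = 49, seed = 9)
  expect_gte(mt$p, 1 / 50)
  expect_lte(mt$p, 1)
  cd <- cadm_test(list(d1, d2), n_perm = 49, seed = 9)
  expect_gte(cd$p_global, 1 / 50)
  expect_lte(cd$p_global, 1)
})

test_that("exact enumeration matches Monte Carlo in the small-n limit", {
  d1 <- random_dist(4, 41)
  d2 <- random_dist(4, 42)
  ex <- mantel_test(d1, d2, seed = 1, exact = TRUE)
  orc <- oracle_mantel_exact(d1, d2)
  expect_equal(ex$p, orc$p)
  expect_equal(ex$t, orc$t, tolerance = 1e-12)
})

test_that("congruence report emits one row per marker and mode", {
  d <- generate_congruent_dataset(4, 10, seed = 55)
  rep1 <- congruence_report(d$morph_dist,
                            list(m1 = d$genetic_dist, m2 = d$genetic_dist),
                            modes = c("raw", "topological"),
                            n_perm = 99, seed = 2)
  expect_equal(nrow(rep1), 4)
  expect_true(all(is.na(rep1$error)))
  expect_true(all(rep1$kendall_W >= 0 & rep1$kendall_W <= 1))

  # topological mode of the morphology tree against itself is perfectly
  # concordant
  self <- congruence_report(d$morph_dist, list(self = d$morph_dist),
                            modes = "topological", n_perm = 99, seed = 3)
  expect_equal(self$kendall_W, 1, tolerance = 1e-12)

  # a failing row is reported but does not abort the others
  bad <- random_dist(10, 77)
  rownames(bad) <- colnames(bad) <- paste0("other", 1:10)
  rep2 <- congruence_report(d$morph_dist,
                            list(ok = d$genetic_dist, bad = bad),
                            modes = "raw", n_perm = 49, seed = 4)
  expect_true(is.na(rep2$error[1]))
  expect_match(rep2$error[2], "labels")
  expect_false(is.na(rep2$mantel_r[1]))
  expect_true(is.na(rep2$mantel_r[2]))
})

test_that("allele-level trees collapse inside the topological pipeline", {
  # two het samples, two hom: allele tree over 6 leaves
  tr <- read_newick("(((X-1,X-2),(Y-1,Z)),(Y-2,V));")
  gm <- list(X = c("X-1", "X-2"), Y = c("Y-1", "Y-2"), Z = "Z", V = "V")
  td <- topological_distances(tr)
  cs <- collapse_allele_distances(td, gm)
  morph <- random_dist(4, 91)
  rownames(morph) <- colnames(morph) <- c("X", "Y", "Z", "V")
  rep <- congruence_report(morph, list(mk = list(tree = tr,
                                                 genotype_map = gm)),
                           modes = "topological", n_perm = 99, seed = 5)
  expect_true(is.na(rep$error[1]))
  # X vs Z: alleles X-1,X-2 vs Z at distances 3,3 -> 3 (duplicated Z)
  expect_equal(cs["X", "Z"], mean(c(td["X-1", "Z"], td["X-2", "Z"])))
})
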