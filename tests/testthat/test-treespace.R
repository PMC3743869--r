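test_that("average linkage reproduces the hand-worked example", {
  d <- dist_matrix(matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
                          dimnames = list(c("A", "B", "C"),
                                          c("A", "B", "C"))))
  tr <- average_linkage_tree(d)
  expect_equal(tr$height, c(1, 4))
  cd <- cophenetic_distances(tr)
  expect_equal(cd["A", "B"], 2)
  expect_equal(cd["A", "C"], 8)

  two <- dist_matrix(matrix(c(0, 3, 3, 0), 2, 2,
                            dimnames = list(c("x", "y"), c("x", "y"))))
  t2 <- average_linkage_tree(two)
  expect_equal(t2$height, 1.5)

  bad <- unclass(d)
  bad[1, 2] <- bad[2, 1] <- NA
  expect_error(average_linkage_tree(bad), "NA")
})

test_that("dendrograms agree with naive and hclust oracles", {
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    d <- random_dist(n, 500 + rep)
    tr <- average_linkage_tree(d)
    orc <- oracle_upgma(d)
    expect_equal(sort(2 * tr$height), orc$heights, tolerance = 1e-10)
    expect_equal(unclass(cophenetic_distances(tr)), orc$cophenetic,
                 tolerance = 1e-10)
    hc <- stats::hclust(stats::as.dist(unclass(d)), method = "average")
    expect_equal(unclass(cophenetic_distances(tr))[rownames(d), rownames(d)],
                 as.matrix(stats::cophenetic(hc))[rownames(d), rownames(d)],
                 tolerance = 1e-10)
  }
})

test_that("UPGMA trees are ultrametric (three-point condition)", {
  for (rep in 1:10) {
    d <- random_dist(7, 900 + rep)
    cd <- cophenetic_distances(average_linkage_tree(d))
    n <- nrow(cd)
    for (i in 1:(n - 2)) {
      for (j in (i + 1):(n - 1)) {
        for (k in (j + 1):n) {
          trip <- sort(c(cd[i, j], cd[i, k], cd[j, k]), decreasing = TRUE)
          expect_equal(trip[1], trip[2], tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("ties are broken deterministically by member labels", {
  d <- matrix(2, 4, 4, dimnames = list(letters[4:1], letters[4:1]))
  diag(d) <- 0
  t1 <- average_linkage_tree(dist_matrix(d))
  t2 <- average_linkage_tree(dist_matrix(d[4:1, 4:1]))
  expect_identical(write_newick(t1), write_newick(t2))
})

test_that("topological distances count edges through the root", {
  t1 <- read_newick("((A,B),(C,D));")
  m1 <- topological_distances(t1)
  expect_equal(m1["A", "B"], 2)
  expect_equal(m1["A", "C"], 4)

  cat4 <- read_newick("(((A,B),C),D);")
  m2 <- topological_distances(cat4)
  expect_equal(m2["A", "D"], 4)
  expect_equal(m2["C", "D"], 3)
})

test_that("topological distances match graph search on random trees", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    tr <- ape::rtree(n)
    m <- topological_distances(tr)
    orc <- oracle_topo_dist(tr)
    expect_equal(unclass(m)[rownames(orc), rownames(orc)], orc)
    # invariant to branch length rescaling
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * 7 + 0.3
    expect_identical(unclass(topological_distances(tr2)), unclass(m))
    # bounded by 2(n-1) for a rooted bifurcating tree
    expect_lte(max(m), 2 * (n - 1))
    expect_true(all(unclass(m)[upper.tri(m)] >= 2))
  }
})

test_that("allele-level distances collapse with homozygote duplication", {
  d <- dist_matrix(matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
                          dimnames = list(c("x-1", "x-2", "y"),
                                          c("x-1", "x-2", "y"))))
  out <- collapse_allele_distances(d, list(X = c("x-1", "x-2"), Y = "y"))
  expect_equal(out["X", "Y"], 5) # mean of (4,4,6,6)
  expect_equal(out["X", "X"], 0)
  expect_equal(unclass(out), t(unclass(out)))

  # all-homozygote: a relabeled copy
  d2 <- random_dist(4, 4)
  rownames(d2) <- colnames(d2) <- paste0("a", 1:4)
  out2 <- collapse_allele_distances(d2, list(S1 = "a1", S2 = "a2",
                                             S3 = "a3", S4 = "a4"))
  expect_equal(unname(unclass(out2)), unname(unclass(d2)))

  expect_error(collapse_allele_distances(d, list(X = c("x-1", "x-2"))),
               "not mapped")
  expect_error(collapse_allele_distances(d, list(X = c("x-1", "x-2"),
                                                 Y = "y", Z = "zz")),
               "absent")
})

test_that("newick parsing validates input and round-trips", {
  tr <- read_newick("((A,B),(C,D));")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  rt <- read_newick(write_newick(tr))
  expect_identical(unclass(topological_distances(rt)),
                   unclass(topological_distances(tr)))

  tb <- read_newick("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_equal(sort(tb$edge.length), c(0.05, 0.1, 0.2, 0.3))
  out <- write_newick(tb)
  tb2 <- read_newick(out)
  expect_equal(sort(tb2$edge.length), sort(tb$edge.length))

  expect_error(read_newick("((A,B);"), "parenthes")
  expect_error(read_newick("((A,B),(A,C));"), "duplicate")

  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  expect_identical(unclass(topological_distances(read_newick(f, file = TRUE))),
                   unclass(topological_distances(tr)))
})
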