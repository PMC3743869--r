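test_that("p-distance counts differing sites with pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("AC-T", "ACGT"), 0) # 3 comparable, 0 different
  expect_equal(p_distance("acgt", "ACGA"), 0.25) # case-insensitive
  expect_warning(d <- p_distance("ACRT", "ACGT"), "ambiguity")
  expect_equal(d, 0) # R treated as N, site dropped
  expect_error(p_distance("ACG", "ACGT"), "aligned length")
  expect_error(p_distance("--NN", "ACGT"), "comparable")
})

test_that("sample distance averages the four inter-allele comparisons", {
  # homozygote vs homozygote: duplication is a no-op
  x <- sample_genotype("x", "AAAAAAAAAA")
  y <- sample_genotype("y", "AAAAAAAATT")
  expect_equal(sample_distance(x, y), 0.2)

  # heterozygote vs homozygote: d(x1,y)=0.1, d(x2,y)=0.3 -> 0.2
  het <- sample_genotype("h", c("AAAAAAAAAT", "AAAAAAATTT"))
  hom <- sample_genotype("y", "AAAAAAAAAA")
  expect_equal(p_distance(het$alleles[1], hom$alleles[1]), 0.1)
  expect_equal(p_distance(het$alleles[2], hom$alleles[1]), 0.3)
  expect_equal(sample_distance(het, hom), 0.2)

  # self-comparison of a heterozygote averages to half its allele distance
  expect_equal(sample_distance(het, het),
               p_distance(het$alleles[1], het$alleles[2]) / 2)
})

test_that("genetic distance matrix matches a brute-force oracle", {
  set.seed(33)
  rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                collapse = "")
  gts <- lapply(1:10, function(i) {
    nall <- sample(1:2, 1)
    sample_genotype(paste0("s", i), vapply(seq_len(nall),
                                           function(k) rand_seq(60), ""))
  })
  gd <- genetic_distance_matrix(gts)
  # oracle: explicit four-comparison enumeration
  for (i in 1:9) {
    for (j in (i + 1):10) {
      ai <- rep(gts[[i]]$alleles, length.out = 2)
      aj <- rep(gts[[j]]$alleles, length.out = 2)
      vals <- c(p_distance(ai[1], aj[1]), p_distance(ai[1], aj[2]),
                p_distance(ai[2], aj[1]), p_distance(ai[2], aj[2]))
      expect_equal(gd[i, j], mean(vals), tolerance = 1e-12)
    }
  }
  expect_true(all(diag(unclass(gd)) == 0))
  expect_equal(unclass(gd), t(unclass(gd)))
  # all-homozygote set reduces to the plain allele p-distance matrix
  homs <- lapply(1:4, function(i) sample_genotype(paste0("h", i),
                                                  rand_seq(40)))
  ghom <- genetic_distance_matrix(homs)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(ghom[i, j],
                   p_distance(homs[[i]]$alleles, homs[[j]]$alleles))
    }
  }
  dup <- c(gts[1], gts[1])
  expect_error(genetic_distance_matrix(dup), "duplicate")
})

test_that("sample distances are symmetric, bounded and species-ordered", {
  set.seed(13)
  for (rep in 1:10) {
    s <- simulate_genotypes(3, 2, seq_length = 200, divergence = 0.1,
                            heterozygosity = 0.5, seed = 100 + rep)
    gd <- genetic_distance_matrix(s$genotypes)
    sp <- s$species[rownames(gd)]
    between <- mean(unclass(gd)[outer(sp, sp, `!=`) & upper.tri(gd)])
    within <- mean(unclass(gd)[outer(sp, sp, `==`) & upper.tri(gd)])
    expect_gt(between, within)
  }
})

test_that("FASTA round-trip preserves the allele-suffix convention", {
  gts <- list(sample_genotype("Car436", c("ACGTACGTAC", "ACGAACGTAC")),
              sample_genotype("Dec001", "ACGTACGTAC"))
  f <- tempfile(fileext = ".fasta")
  write_genotypes_fasta(gts, f)
  lines <- readLines(f)
  expect_true(any(grepl("^>Car436-1$", lines)))
  expect_true(any(grepl("^>Car436-2$", lines)))
  expect_true(any(grepl("^>Dec001$", lines)))
  back <- read_genotypes_fasta(f)
  ids <- vapply(back, `[[`, "", "sample_id")
  expect_setequal(ids, c("Car436", "Dec001"))
  expect_equal(toupper(back[[match("Car436", ids)]]$alleles),
               gts[[1]]$alleles)
})
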