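BASES <- c("A", "C", "G", "T")

# evolve an integer-coded sequence along a branch of `t` expected
# substitutions/site under the equal-rates (Jukes-Cantor) model
jc_evolve <- function(seq_int, t) {
  if (t <= 0) return(seq_int)
  p_diff <- 0.75 * (1 - exp(-4 * t / 3))
  hit <- runif(length(seq_int)) < p_diff
  if (any(hit)) {
    shift <- sample.int(3, sum(hit), replace = TRUE)
    seq_int[hit] <- ((seq_int[hit] - 1 + shift) %% 4) + 1
  }
  seq_int
}

#' Expected p-distance under the equal-rates substitution model
#'
#' Closed-form expectation of the proportion of differing sites between two
#' sequences whose connecting path has `t` expected substitutions per site:
#' `3/4 (1 - exp(-4t/3))`.
#'
#' @param t total path length in substitutions/site.
#' @return expected p-distance.
#' @export
expected_p_distance <- function(t) 0.75 * (1 - exp(-4 * t / 3))

#' Simulate diploid allele data for several species
#'
#' Emulates nuclear-intron (EPIC-style) allele data: a star species tree of
#' pairwise depth `divergence`, alleles evolved site-i.i.d. under the
#' equal-rates model, samples heterozygous with probability
#' `heterozygosity` (homozygotes store a single allele), and optional hybrid
#' samples whose two alleles descend from two distinct species lineages.
#'
#' @param n_per_species samples per species; scalar or vector of length
#'   `n_species`.
#' @param n_species number of species.
#' @param seq_length aligned sites (>= 50).
#' @param divergence expected substitutions/site separating two species'
#'   ancestral sequences.
#' @param heterozygosity probability a (non-hybrid) sample is heterozygous.
#' @param hybrid_samples number of hybrid samples (requires >= 2 species);
#'   hybrids replace the first samples of species 1, 2, ... and are always
#'   heterozygous.
#' @param within_divergence expected substitutions/site separating two
#'   alleles of the same species (default `divergence/10`).
#' @param seed integer seed; the dataset is a pure function of
#'   (params, seed).
#' @return list with `genotypes` (list of [sample_genotype()]), `species`
#'   (named character vector sample -> species), `hybrids` (sample ids),
#'   `tree` (the generating allele tree, class `phylo`) and `params`.
#'   Expected pairwise p-distances follow from the tree via
#'   [expected_p_distance()]: `divergence + within_divergence` between
#'   species, `within_divergence` within.
#' @export
simulate_genotypes <- function(n_per_species, n_species, seq_length = 300,
                               divergence = 0.05, heterozygosity = 0.3,
                               hybrid_samples = 0,
                               within_divergence = divergence / 10,
                               seed = 1) {
  if (seq_length < 50) stop("seq_length must be >= 50")
  if (heterozygosity < 0 || heterozygosity > 1) {
    stop("heterozygosity must be in [0, 1]")
  }
  if (hybrid_samples > 0 && n_species < 2) {
    stop("hybrid samples require at least 2 species")
  }
  counts <- rep(n_per_species, length.out = n_species)
  sp_labels <- sprintf("Sp%d", seq_len(n_species))

  with_seed(seed, {
    root <- sample.int(4, seq_length, replace = TRUE)
    anc <- lapply(seq_len(n_species), function(k) jc_evolve(root, divergence / 2))
    new_allele <- function(k) jc_evolve(anc[[k]], within_divergence / 2)

    genotypes <- list()
    species <- character(0)
    hybrids <- character(0)
    tips <- list() # for the generating tree: tip label + species of origin
    hyb_left <- hybrid_samples
    for (k in seq_len(n_species)) {
      for (i in seq_len(counts[k])) {
        sid <- sprintf("%s_%02d", sp_labels[k], i)
        if (hyb_left > 0 && i == 1) {
          other <- (k %% n_species) + 1
          alle <- list(new_allele(k), new_allele(other))
          origin <- c(k, other)
          hyb_left <- hyb_left - 1
          hybrids <- c(hybrids, sid)
        } else if (runif(1) < heterozygosity) {
          alle <- list(new_allele(k), new_allele(k))
          origin <- c(k, k)
        } else {
          alle <- list(new_allele(k))
          origin <- k
        }
        txt <- vapply(alle, function(s) paste(BASES[s], collapse = ""), "")
        genotypes[[sid]] <- sample_genotype(sid, txt, species = sp_labels[k])
        species[sid] <- sp_labels[k]
        suffix <- if (length(txt) == 2) c("-1", "-2") else ""
        for (ai in seq_along(txt)) {
          tips[[length(tips) + 1]] <- list(label = paste0(sid, suffix[ai]),
                                           species = origin[ai])
        }
      }
    }
    if (hyb_left > 0) {
      stop("not enough species with samples to place all hybrid samples")
    }
    # generating allele tree: star species tree, alleles hanging below
    sub <- vapply(seq_len(n_species), function(k) {
      mine <- Filter(function(tp) tp$species == k, tips)
      if (length(mine) == 0) return(NA_character_)
      leaves <- paste0(vapply(mine, `[[`, "", "label"), ":",
                       format(within_divergence / 2, digits = 10),
                       collapse = ",")
      paste0("(", leaves, "):",
             format(divergence / 2 - within_divergence / 2, digits = 10))
    }, "")
    sub <- sub[!is.na(sub)]
    tree <- ape::read.tree(text = paste0("(", paste(sub, collapse = ","), ");"))

    list(genotypes = unname(genotypes), species = species,
         hybrids = hybrids, tree = tree,
         params = list(n_per_species = counts, n_species = n_species,
                       seq_length = seq_length, divergence = divergence,
                       heterozygosity = heterozygosity,
                       hybrid_samples = hybrid_samples,
                       within_divergence = within_divergence, seed = seed))
  })
}

#' Generate a morphology/genetics dataset with tunable congruence
#'
#' Draws per-sample morphological trait vectors from species-specific
#' multivariate normals (unit within-species standard deviation) whose
#' between-species mean separation scales with `effect_size`, and genetic
#' distances from [simulate_genotypes()] on the same species assignment.
#' `effect_size = 0` makes the morphological features independent of species
#' — and hence of the genetic matrix — which is the null configuration used
#' for permutation-test calibration.
#'
#' @param effect_size >= 0; species mean separation in within-species s.d.
#'   units.
#' @param n_samples total samples (>= 4).
#' @param seed integer seed.
#' @param n_species number of species (default 3).
#' @param n_traits number of morphological traits (default 3).
#' @param ... further arguments passed to [simulate_genotypes()].
#' @return list with `features` (samples x traits matrix), `morph_dist` and
#'   `genetic_dist` ([dist_matrix()]s with identical label order), and
#'   `species`.
#' @export
generate_congruent_dataset <- function(effect_size, n_samples, seed,
                                       n_species = 3, n_traits = 3, ...) {
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (n_samples < 4) stop("need at least 4 samples")
  counts <- diff(floor(seq(0, n_samples, length.out = n_species + 1)))
  sim <- simulate_genotypes(counts, n_species, seed = seed + 1L, ...)
  ids <- names(sim$species)
  kidx <- as.integer(factor(sim$species, levels = unique(sim$species)))
  with_seed(seed, {
    means <- matrix(0, n_species, n_traits)
    for (k in seq_len(n_species)) {
      means[k, ((k - 1) %% n_traits) + 1] <- effect_size
    }
    feats <- means[kidx, , drop = FALSE] +
      matrix(rnorm(n_samples * n_traits), n_samples, n_traits)
    rownames(feats) <- ids
    colnames(feats) <- paste0("trait", seq_len(n_traits))
    gd <- genetic_distance_matrix(sim$genotypes)
    gd <- dist_matrix(unclass(gd)[ids, ids])
    list(features = feats,
         morph_dist = dist_matrix(as.matrix(stats::dist(feats))),
         genetic_dist = gd,
         species = sim$species)
  })
}
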