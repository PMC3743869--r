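#!/usr/bin/env Rscript
# Step 3: simulated nuclear-intron markers on the same colonies. Two
# diploid markers are generated on the species assignment of step 1 (one
# with a hybrid sample carrying alleles from two species), written as
# FASTA with the <Sample>-1/<Sample>-2 allele-suffix convention, and
# collapsed to sample-level p-distance matrices with homozygote
# duplication / four-comparison averaging.

library(phylomorph)

out <- "results"
cfg <- demo_config(seed = 1, n_colonies = 4)
truth <- read.csv(file.path(out, "colony_truth.csv"))
counts <- as.integer(table(factor(truth$species, levels = unique(truth$species))))

mseed <- cfg$seed + 1000L
for (mk in cfg$markers) {
  mseed <- mseed + 1L
  sim <- simulate_genotypes(n_per_species = counts,
                            n_species = length(counts),
                            seq_length = mk$seq_length,
                            divergence = mk$divergence,
                            heterozygosity = mk$heterozygosity,
                            hybrid_samples = mk$hybrid_samples,
                            seed = mseed)
  # keep sample ids identical to the colony ids (same species order)
  for (k in seq_along(sim$genotypes)) {
    sim$genotypes[[k]]$sample_id <- truth$colony_id[k]
  }
  write_genotypes_fasta(sim$genotypes,
                        file.path(out, paste0(mk$name, ".fasta")))
  gd <- genetic_distance_matrix(sim$genotypes)
  write_dist_csv(gd, file.path(out, paste0(mk$name, "_distances.csv")))
  nhet <- sum(vapply(sim$genotypes, function(g) length(g$alleles), 0L) == 2)
  message(sprintf("%s: %d samples (%d heterozygous, %d hybrid), mean p-distance %.4f",
                  mk$name, length(sim$genotypes), nhet,
                  length(sim$hybrids), mean(unroll(gd))))
}
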