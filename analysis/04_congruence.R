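#!/usr/bin/env Rscript
# Step 4: congruence between colony morphology and the simulated molecular
# markers. For every marker, in raw and topological (unit-branch-length
# cophenetic) mode, compute the Mantel statistic (standardized deviate t
# with permutation p) and the CADM statistics (Kendall's W with global
# permutation p; a posteriori Mantel correlation on ranks with its p),
# with 1000 permutations per test.

library(phylomorph)

out <- "results"
md <- read_dist_csv(file.path(out, "morph_distances.csv"))
markers <- sub("_distances\\.csv$", "",
               basename(list.files(out, pattern = "marker.*_distances\\.csv$")))
gen <- lapply(markers, function(mk) {
  list(dist = read_dist_csv(file.path(out, paste0(mk, "_distances.csv"))))
})
names(gen) <- markers

report <- congruence_report(md, gen, modes = c("raw", "topological"),
                            n_perm = 1000, seed = 1)
write.csv(report, file.path(out, "congruence_report.csv"), row.names = FALSE)

disp <- report[, c("comparison", "mode", "mantel_t", "mantel_p",
                   "kendall_W", "kendall_p", "cadm_r", "cadm_p")]
disp[, -(1:2)] <- round(disp[, -(1:2)], 3)
print(disp, row.names = FALSE)
sig <- report$mantel_p < 0.05 & report$kendall_p < 0.05
message(sprintf("%d of %d comparisons significant (p < 0.05) for both tests",
                sum(sig), nrow(report)))
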