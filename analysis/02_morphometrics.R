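#!/usr/bin/env Rscript
# Step 2: whole-colony morphometrics. Each volume is skeletonized to its
# medial-axis curve graph; branch-level measures (da, db, dc, b_angle,
# g_angle, rb, br_spacing) are aggregated into the three colony traits
# (branch thickness, branch spacing, branch length-to-thickness ratio);
# traits are standardized and turned into the Euclidean morphological
# distance matrix and its average-linkage (UPGMA) dendrogram.

library(phylomorph)

out <- "results"
vol_dirs <- list.dirs(file.path(out, "volumes"), recursive = FALSE)
stopifnot(length(vol_dirs) > 0)

features <- list()
branch_tables <- list()
for (vd in vol_dirs) {
  cid <- basename(vd)
  vol <- read_volume_tiff(vd)
  sk <- skeletonize(vol)
  meas <- measure_branches(sk)
  meas$colony_id <- cid
  branch_tables[[cid]] <- meas
  features[[cid]] <- aggregate_features(meas, cid)
  message(sprintf("%s: %d branches, thickness %.2f mm, spacing %.2f mm, ratio %.2f",
                  cid, nrow(meas), features[[cid]]$thickness,
                  features[[cid]]$spacing,
                  features[[cid]]$length_thickness_ratio))
}
features <- do.call(rbind, features)
write.csv(do.call(rbind, branch_tables),
          file.path(out, "branch_measures.csv"), row.names = FALSE)
write.csv(features, file.path(out, "colony_features.csv"), row.names = FALSE)

truth <- read.csv(file.path(out, "colony_truth.csv"))
cmp <- merge(features, truth, by = "colony_id")
message(sprintf("thickness recovery: mean |error| %.1f%% of truth",
                100 * mean(abs(cmp$thickness - cmp$true_mean_diameter) /
                             cmp$true_mean_diameter)))

fm <- normalize_features(features)
md <- morphological_distances(fm)
write_dist_csv(md, file.path(out, "morph_distances.csv"))
write_dist_phylip(md, file.path(out, "morph_distances.phy"))
tree <- average_linkage_tree(md)
write_newick(tree, file.path(out, "morph_tree.nwk"))
message("morphological tree: ", write_newick(tree))
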