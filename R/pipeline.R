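#' Default demonstration configuration
#'
#' Three synthetic species with distinct branch thickness, spacing and
#' length-to-thickness ratio, plus two simulated diploid markers whose
#' species assignment matches the colonies. Used by the end-to-end pipeline
#' and the analysis scripts; every value can be overridden by supplying a
#' modified copy to [run_pipeline()].
#'
#' @param seed integer master seed.
#' @param n_colonies colonies per species.
#' @param n_perm permutations per congruence test.
#' @return a nested configuration list.
#' @export
demo_config <- function(seed = 1, n_colonies = 4, n_perm = 1000) {
  list(
    seed = seed,
    n_perm = n_perm,
    out_dir = NULL,
    spacing = c(0.33, 0.33, 1.50),
    prune_length = NULL,
    aggregation = "mean",
    diameter = "interior",
    modes = c("raw", "topological"),
    jitter = list(angle_sd = 4, length_cv = 0.08, radius_cv = 0.05),
    species = list(
      list(name = "Sp1", n_colonies = n_colonies, mean_radius = 4,
           mean_branch_length = 22, branch_angle = 55, n_generations = 3),
      list(name = "Sp2", n_colonies = n_colonies, mean_radius = 2,
           mean_branch_length = 18, branch_angle = 45, n_generations = 3),
      list(name = "Sp3", n_colonies = n_colonies, mean_radius = 3,
           mean_branch_length = 34, branch_angle = 35, n_generations = 3)),
    markers = list(
      list(name = "markerA", seq_length = 300, divergence = 0.08,
           heterozygosity = 0.3, hybrid_samples = 0),
      list(name = "markerB", seq_length = 300, divergence = 0.05,
           heterozygosity = 0.3, hybrid_samples = 1)))
}

#' Run the full morphology-vs-phylogeny pipeline
#'
#' Orchestrates the end-to-end analysis: colony volumes (read from TIFF
#' stacks or generated from the synthetic species configuration) are
#' skeletonized and measured; the three colony traits are normalized and
#' turned into a Euclidean morphological distance matrix and a UPGMA tree;
#' genetic inputs (FASTA files or simulated markers on the same species
#' assignment) become sample-level p-distance matrices; Mantel and CADM
#' congruence statistics are computed for every marker in raw and
#' topological mode. All artifacts are written under `config$out_dir` when
#' set, together with a provenance log recording the configuration, seed
#' and package version. Deterministic given (config, seed).
#'
#' @param config configuration list as from [demo_config()], or the path to
#'   a YAML file holding one.
#' @return (invisibly) a list with `features`, `feature_matrix`,
#'   `morph_dist`, `morph_tree`, `genetic` (per-marker genotype sets and
#'   distance matrices), `report` (the congruence table) and `truth`
#'   (per-colony blueprint ground truth, synthetic colonies only).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is required")
  seed <- as.integer(config$seed)
  n_perm <- if (is.null(config$n_perm)) 1000 else config$n_perm
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- stage 1: colony volumes -------------------------------------------
  volumes <- list()
  species_of <- character(0)
  truth <- list()
  if (!is.null(config$volumes)) {
    volumes <- stage("read_volumes", lapply(config$volumes, read_volume_tiff))
    if (is.null(names(volumes))) {
      names(volumes) <- paste0("colony", seq_along(volumes))
    }
    species_of <- stats::setNames(sub("_[0-9]+$", "", names(volumes)),
                                  names(volumes))
  } else if (!is.null(config$species)) {
    jit <- config$jitter
    cseed <- seed
    for (sp in config$species) {
      for (i in seq_len(sp$n_colonies)) {
        cid <- sprintf("%s_%02d", sp$name, i)
        cseed <- cseed + 1L
        bp <- stage("generate_colonies", generate_colony_blueprint(
          species_params = sp[c("mean_radius", "mean_branch_length",
                                "branch_angle", "n_generations")],
          seed = cseed, species_label = sp$name,
          angle_jitter_sd = jit$angle_sd, length_cv = jit$length_cv,
          radius_cv = jit$radius_cv))
        volumes[[cid]] <- stage("rasterize", rasterize(bp, config$spacing))
        truth[[cid]] <- blueprint_truth(bp)
        species_of[cid] <- sp$name
      }
    }
  } else {
    stop("config must provide either `volumes` or `species`")
  }

  # ---- stage 2: morphometrics --------------------------------------------
  features <- stage("morphometrics", do.call(rbind, lapply(
    names(volumes), function(cid) {
      sk <- skeletonize(volumes[[cid]], prune_length = config$prune_length)
      meas <- measure_branches(sk)
      aggregate_features(meas, cid, stat = config$aggregation,
                         diameter = config$diameter)
    })))
  fm <- stage("normalize", normalize_features(features))
  md <- stage("distances", morphological_distances(fm))
  tree <- stage("upgma", average_linkage_tree(md))

  # ---- stage 3: genetics --------------------------------------------------
  genetic <- list()
  gen_inputs <- list()
  if (!is.null(config$fasta)) {
    for (nm in names(config$fasta)) {
      gt <- stage("read_genotypes", read_genotypes_fasta(config$fasta[[nm]]))
      gd <- stage("genetic_distances", genetic_distance_matrix(gt))
      genetic[[nm]] <- list(genotypes = gt, dist = gd)
      gen_inputs[[nm]] <- list(dist = gd)
    }
  } else if (!is.null(config$markers)) {
    counts <- as.integer(table(factor(species_of,
                                      levels = unique(species_of))))
    mseed <- seed + 1000L
    for (mk in config$markers) {
      mseed <- mseed + 1L
      sim <- stage("simulate_genotypes", simulate_genotypes(
        n_per_species = counts, n_species = length(counts),
        seq_length = mk$seq_length, divergence = mk$divergence,
        heterozygosity = mk$heterozygosity,
        hybrid_samples = mk$hybrid_samples, seed = mseed))
      # rename simulated samples to the colony ids (same species order)
      ids <- names(volumes)
      for (k in seq_along(sim$genotypes)) {
        sim$genotypes[[k]]$sample_id <- ids[k]
      }
      names(sim$species) <- ids
      gd <- stage("genetic_distances", genetic_distance_matrix(sim$genotypes))
      genetic[[mk$name]] <- list(sim = sim, dist = gd)
      gen_inputs[[mk$name]] <- list(dist = gd)
    }
  }

  # ---- stage 4: congruence ------------------------------------------------
  report <- if (length(gen_inputs)) {
    stage("congruence", congruence_report(md, gen_inputs,
                                          modes = config$modes,
                                          n_perm = n_perm, seed = seed))
  } else {
    NULL
  }

  # ---- artifacts -----------------------------------------------------------
  if (!is.null(out_dir)) {
    utils::write.csv(features, file.path(out_dir, "colony_features.csv"),
                     row.names = FALSE)
    write_dist_csv(md, file.path(out_dir, "morph_distances.csv"))
    write_dist_phylip(md, file.path(out_dir, "morph_distances.phy"))
    write_newick(tree, file.path(out_dir, "morph_tree.nwk"))
    for (nm in names(genetic)) {
      write_dist_csv(genetic[[nm]]$dist,
                     file.path(out_dir, paste0(nm, "_distances.csv")))
      if (!is.null(genetic[[nm]]$sim)) {
        write_genotypes_fasta(genetic[[nm]]$sim$genotypes,
                              file.path(out_dir, paste0(nm, ".fasta")))
      }
    }
    if (!is.null(report)) {
      utils::write.csv(report, file.path(out_dir, "congruence_report.csv"),
                       row.names = FALSE)
    }
    prov <- list(package = "phylomorph",
                 version = as.character(utils::packageVersion("phylomorph")),
                 seed = seed, n_perm = n_perm,
                 aggregation = config$aggregation,
                 diameter = config$diameter,
                 sd_convention = "sample (n-1)",
                 config = config[setdiff(names(config), "out_dir")])
    yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  }

  invisible(list(features = features, feature_matrix = fm, morph_dist = md,
                 morph_tree = tree, genetic = genetic, report = report,
                 truth = truth, species = species_of))
}
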