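all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

sum_cross <- function(m1, m2) sum(m1 * m2) / 2 # zero diagonal, symmetric

#' Mantel permutation test between two distance matrices
#'
#' The raw statistic is the cross-product `Z = sum_{i<j} d1_ij d2_ij`; the
#' standardized Mantel correlation `r` is the Pearson correlation of the
#' unrolled upper triangles. The null distribution is obtained by
#' simultaneously permuting rows and columns of `d2`; `t` is the
#' permutation-standardized deviate `(Z - mean(Z_null)) / sd(Z_null)`.
#' P-values use the add-one convention `p = (1 + #(null >= obs)) /
#' (n_perm + 1)`, so the minimum attainable p is `1/(n_perm+1)`. With
#' `exact = TRUE` all `n!` permutations are enumerated instead and
#' `p = #(null >= obs) / n!` (the identity permutation is in the
#' enumeration).
#'
#' @param d1,d2 [dist_matrix()]s with identical labels in identical order.
#' @param n_perm number of random permutations (ignored when `exact`).
#' @param seed integer seed for the permutation draws.
#' @param tail `"greater"` (congruence, default), `"less"` or
#'   `"two-sided"` (on the deviate from the null mean).
#' @param exact enumerate all permutations (n <= 8).
#' @return object of class `mantel_result`: `Z`, `r`, `t`, `p`, `tail`,
#'   `n_perm`, `exact`, `seed`.
#' @export
mantel_test <- function(d1, d2, n_perm = 1000, seed,
                        tail = c("greater", "less", "two-sided"),
                        exact = FALSE) {
  tail <- match.arg(tail)
  d1 <- dist_matrix(d1)
  d2 <- dist_matrix(d2)
  check_same_labels(list(d1, d2))
  n <- nrow(d1)
  if (n < 4) stop("need at least 4 objects")
  if (!exact && n_perm < 1) stop("n_perm must be >= 1")
  v1 <- unroll(d1)
  v2 <- unroll(d2)
  if (sd(v1) == 0) stop("matrix `d1` is constant: r undefined")
  if (sd(v2) == 0) stop("matrix `d2` is constant: r undefined")
  m1 <- unclass(d1)
  m2 <- unclass(d2)
  Z <- sum_cross(m1, m2)
  r <- cor(v1, v2)
  znull <- if (exact) {
    if (n > 8) stop("exact enumeration supported for n <= 8")
    P <- all_permutations(n)
    vapply(seq_len(nrow(P)), function(k) {
      p <- P[k, ]
      sum_cross(m1, m2[p, p])
    }, 0)
  } else {
    with_seed(seed, vapply(seq_len(n_perm), function(k) {
      p <- sample.int(n)
      sum_cross(m1, m2[p, p])
    }, 0))
  }
  mu <- mean(znull)
  s <- sd(znull)
  tstat <- if (s > 0) (Z - mu) / s else NA_real_
  eps <- 1e-12 * max(1, abs(Z))
  count <- switch(tail,
                  greater = sum(znull >= Z - eps),
                  less = sum(znull <= Z + eps),
                  `two-sided` = sum(abs(znull - mu) >= abs(Z - mu) - eps))
  p <- if (exact) count / length(znull) else (1 + count) / (n_perm + 1)
  structure(list(Z = Z, r = r, t = tstat, p = p, tail = tail,
                 n_perm = length(znull), exact = exact,
                 seed = if (exact) NA_integer_ else seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): Z = %.6g, r = %.4f, t = %.3f, p = %.4g\n",
              if (x$exact) "exact" else paste0(x$n_perm, " permutations"),
              x$tail, x$Z, x$r, x$t, x$p))
  invisible(x)
}

#' Kendall's coefficient of concordance with tie correction
#'
#' For `m` rank vectors of length `N` (mid-ranks for ties),
#' `W = 12 S / (m^2 (N^3 - N) - m T)` where `S` is the sum of squared
#' deviations of the rank sums from their mean and `T` the tie correction
#' `sum(t^3 - t)` accumulated over tie groups of every row.
#'
#' @param rank_rows matrix (m x N) of ranks, or list of rank vectors.
#' @return W in \[0, 1\].
#' @export
kendall_w <- function(rank_rows) {
  if (is.list(rank_rows)) rank_rows <- do.call(rbind, rank_rows)
  m <- nrow(rank_rows)
  N <- ncol(rank_rows)
  if (m < 2) stop("need at least 2 rank vectors")
  if (any(apply(rank_rows, 1, function(r) length(unique(r)) == 1))) {
    stop("a constant ranking leaves W undefined")
  }
  rs <- colSums(rank_rows)
  S <- sum((rs - mean(rs))^2)
  Tt <- sum(apply(rank_rows, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }))
  12 * S / (m^2 * (N^3 - N) - m * Tt)
}

rank_matrix <- function(d) {
  # symmetric matrix whose off-diagonal entries carry the mid-ranks of the
  # unrolled distances; permuting objects then permutes the ranks directly
  v <- unroll(d)
  r <- rank(v, ties.method = "average")
  n <- nrow(d)
  tm <- matrix(0, n, n)
  tm[lower.tri(tm)] <- r
  m <- t(tm) + tm
  dimnames(m) <- dimnames(d)
  m
}

#' Congruence among distance matrices (CADM)
#'
#' Global test: within each matrix the unrolled distances are converted to
#' mid-ranks; Kendall's W (tie-corrected) over the m rank vectors measures
#' their concordance; the null distribution permutes the objects
#' (rows+columns simultaneously) of every matrix independently. A
#' posteriori, each matrix k gets a Mantel correlation on ranks — the
#' Pearson correlation between its ranks and the mean ranks of the other
#' m-1 matrices — with a p-value from permuting matrix k only (one-tailed,
#' greater). Add-one p-value convention throughout; `exact = TRUE`
#' enumerates all permutations (holding the first matrix fixed for the
#' global test, which is valid because W is invariant under a common
#' relabeling).
#'
#' @param matrices list of >= 2 [dist_matrix()]s, identical labels/order.
#' @param n_perm permutations for both global and a posteriori tests.
#' @param seed integer seed.
#' @param exact enumerate all permutations (small n only).
#' @return object of class `cadm_result`: `W`, `p_global`, `posthoc` (data
#'   frame: matrix, r, p), `n_perm`, `exact`, `seed`.
#' @export
cadm_test <- function(matrices, n_perm = 1000, seed, exact = FALSE) {
  if (length(matrices) < 2) stop("need at least 2 matrices")
  matrices <- lapply(matrices, dist_matrix)
  check_same_labels(matrices)
  m <- length(matrices)
  n <- nrow(matrices[[1]])
  rank_mats <- lapply(matrices, rank_matrix)
  ranks <- do.call(rbind, lapply(rank_mats, unroll))
  W <- kendall_w(ranks)

  # the tie correction only depends on each row's multiset of ranks, which
  # object permutations leave unchanged: precompute it for the null loop
  Tt <- sum(apply(ranks, 1, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  }))
  N <- ncol(ranks)
  w_stat <- function(rr) {
    rs <- colSums(rr)
    12 * sum((rs - mean(rs))^2) / (m^2 * (N^3 - N) - m * Tt)
  }

  perm_ranks <- function(k, p) unroll(rank_mats[[k]][p, p])

  if (exact) {
    if (n > 6) stop("exact enumeration supported for n <= 6")
    P <- all_permutations(n)
    np <- nrow(P)
    # global: matrix 1 fixed, matrices 2..m take every permutation
    combos <- do.call(expand.grid, rep(list(seq_len(np)), m - 1))
    wnull <- vapply(seq_len(nrow(combos)), function(ci) {
      rr <- ranks
      for (k in 2:m) {
        rr[k, ] <- perm_ranks(k, P[combos[ci, k - 1], ])
      }
      w_stat(rr)
    }, 0)
    p_global <- sum(wnull >= W - 1e-12) / length(wnull)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    wnull <- with_seed(seed, vapply(seq_len(n_perm), function(it) {
      rr <- do.call(rbind, lapply(seq_len(m), function(k) {
        perm_ranks(k, sample.int(n))
      }))
      w_stat(rr)
    }, 0))
    p_global <- (1 + sum(wnull >= W - 1e-12)) / (n_perm + 1)
  }

  posthoc <- data.frame(matrix = if (!is.null(names(matrices))) {
    names(matrices)
  } else paste0("D", seq_len(m)), r = NA_real_, p = NA_real_)
  for (k in seq_len(m)) {
    others <- colMeans(ranks[-k, , drop = FALSE])
    rk <- cor(ranks[k, ], others)
    posthoc$r[k] <- rk
    if (exact) {
      P <- all_permutations(n)
      rnull <- vapply(seq_len(nrow(P)), function(ci) {
        cor(perm_ranks(k, P[ci, ]), others)
      }, 0)
      posthoc$p[k] <- sum(rnull >= rk - 1e-12) / length(rnull)
    } else {
      rnull <- with_seed(seed + k, vapply(seq_len(n_perm), function(it) {
        cor(perm_ranks(k, sample.int(n)), others)
      }, 0))
      posthoc$p[k] <- (1 + sum(rnull >= rk - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(W = W, p_global = p_global, posthoc = posthoc,
                 n_perm = if (exact) length(wnull) else n_perm,
                 exact = exact, seed = if (exact) NA_integer_ else seed),
            class = "cadm_result")
}

#' @export
print.cadm_result <- function(x, ...) {
  cat(sprintf("CADM (%s): W = %.4f, global p = %.4g\n",
              if (x$exact) "exact" else paste0(x$n_perm, " permutations"),
              x$W, x$p_global))
  cat("A posteriori Mantel correlations on ranks:\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Table of congruence statistics for morphology vs genetic inputs
#'
#' Emits one row per genetic input and mode with the three statistic pairs
#' reported in colony morphology / molecular phylogeny comparisons: the
#' Mantel standardized deviate t (with its permutation p), Kendall's W (with
#' the global CADM p) and the CADM a posteriori Mantel correlation on ranks
#' (with its p). Mode `"raw"` compares the distance matrices directly; mode
#' `"topological"` first converts both sides to unit-branch-length
#' cophenetic (edge-count) distances: the morphological side through its
#' UPGMA dendrogram, the genetic side through the supplied tree (alleles
#' collapsed to samples) or, failing that, through a UPGMA dendrogram of the
#' genetic distances. A failing row is reported with its error message;
#' remaining rows are still computed.
#'
#' @param morph morphological [dist_matrix()] over colonies.
#' @param genetic named list of genetic inputs; each element is either a
#'   [dist_matrix()] or a list with any of `dist` (matrix), `tree` (`phylo`
#'   over alleles or samples) and `genotype_map` (sample -> allele labels,
#'   required to collapse an allele-level tree).
#' @param modes subset of `c("raw", "topological")`.
#' @param n_perm permutations per test.
#' @param seed integer seed; row k uses `seed + k` so rows are independent
#'   but reproducible.
#' @return data frame with one row per input x mode.
#' @export
congruence_report <- function(morph, genetic,
                              modes = c("raw", "topological"),
                              n_perm = 1000, seed = 1) {
  morph <- dist_matrix(morph)
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(names(genetic))) {
    names(genetic) <- paste0("marker", seq_along(genetic))
  }
  rows <- list()
  k <- 0L
  for (nm in names(genetic)) {
    for (mode in modes) {
      k <- k + 1L
      row <- data.frame(comparison = nm, mode = mode,
                        mantel_Z = NA_real_, mantel_r = NA_real_,
                        mantel_t = NA_real_, mantel_p = NA_real_,
                        kendall_W = NA_real_, kendall_p = NA_real_,
                        cadm_r = NA_real_, cadm_p = NA_real_,
                        n_perm = n_perm, seed = seed + k,
                        error = NA_character_)
      res <- tryCatch({
        pair <- resolve_comparison(morph, genetic[[nm]], mode)
        mt <- mantel_test(pair$m1, pair$m2, n_perm = n_perm,
                          seed = seed + k)
        cd <- cadm_test(list(morphology = pair$m1, genetic = pair$m2),
                        n_perm = n_perm, seed = seed + k)
        row$mantel_Z <- mt$Z; row$mantel_r <- mt$r
        row$mantel_t <- mt$t; row$mantel_p <- mt$p
        row$kendall_W <- cd$W; row$kendall_p <- cd$p_global
        row$cadm_r <- cd$posthoc$r[2]; row$cadm_p <- cd$posthoc$p[2]
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[k]] <- res
    }
  }
  do.call(rbind, rows)
}

resolve_comparison <- function(morph, input, mode) {
  if (is.matrix(input) || inherits(input, "dist")) {
    input <- list(dist = dist_matrix(as.matrix(input)))
  }
  labels <- rownames(morph)
  align <- function(d) {
    d <- as.matrix(d)
    if (!setequal(rownames(d), labels)) {
      stop("genetic input labels do not match the morphological matrix")
    }
    dist_matrix(d[labels, labels])
  }
  if (mode == "raw") {
    if (is.null(input$dist)) {
      stop("raw mode needs a genetic distance matrix")
    }
    return(list(m1 = morph, m2 = align(input$dist)))
  }
  # topological mode
  m1 <- topological_distances(average_linkage_tree(morph))
  m1 <- dist_matrix(unclass(m1)[labels, labels])
  m2 <- if (!is.null(input$tree)) {
    td <- topological_distances(input$tree)
    if (!is.null(input$genotype_map)) {
      collapse_allele_distances(td, input$genotype_map)
    } else {
      td
    }
  } else if (!is.null(input$dist)) {
    topological_distances(average_linkage_tree(align(input$dist)))
  } else {
    stop("topological mode needs a tree or a distance matrix")
  }
  list(m1 = m1, m2 = align(m2))
}
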