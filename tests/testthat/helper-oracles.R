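# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (double loops, enumeration, graph search) so that
# agreement with the package implementations is informative.

# naive agglomerative average-linkage: clusters as label sets, distances
# recomputed from the original matrix at every step
oracle_upgma <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- numeric(0)
  merges <- list()
  avg_dist <- function(a, b) {
    mean(d[a, b])
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        dd <- avg_dist(clusters[[i]], clusters[[j]])
        if (dd < bestd - 1e-12) {
          bestd <- dd
          best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1]] <- list(a = clusters[[best[1]]],
                                         b = clusters[[best[2]]],
                                         h = bestd)
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  coph <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (m in merges) {
    coph[m$a, m$b] <- m$h
    coph[m$b, m$a] <- m$h
  }
  list(heights = sort(heights), cophenetic = coph)
}

# edge-count distances between tips by breadth-first search on the tree graph
oracle_topo_dist <- function(tree) {
  n <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  dd <- igraph::distances(g, v = seq_len(n), to = seq_len(n), weights = NA)
  dimnames(dd) <- list(tree$tip.label, tree$tip.label)
  dd
}

# exhaustive Mantel permutation null for small n
oracle_mantel_exact <- function(d1, d2) {
  d1 <- as.matrix(d1)
  d2 <- as.matrix(d2)
  n <- nrow(d1)
  perms <- perms_of(n)
  z <- apply(perms, 1, function(p) sum(d1 * d2[p, p]) / 2)
  zobs <- sum(d1 * d2) / 2
  list(z = zobs, p = mean(z >= zobs - 1e-12),
       t = (zobs - mean(z)) / sd(z))
}

perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}

# exhaustive CADM global null for m = 2 (first matrix fixed; W is invariant
# under a common relabeling of both matrices)
oracle_cadm_exact <- function(d1, d2) {
  r1 <- rank(upper_vec(d1), ties.method = "average")
  rm2 <- rank_to_matrix(d2)
  n <- nrow(as.matrix(d1))
  perms <- perms_of(n)
  wfun <- function(r2) {
    rs <- r1 + r2
    S <- sum((rs - mean(rs))^2)
    N <- length(r1)
    tie <- function(r) {
      tt <- table(r)
      sum(tt^3 - tt)
    }
    12 * S / (4 * (N^3 - N) - 2 * (tie(r1) + tie(r2)))
  }
  wobs <- wfun(rank(upper_vec(d2), ties.method = "average"))
  wnull <- apply(perms, 1, function(p) wfun(upper_vec(rm2[p, p])))
  list(W = wobs, p = mean(wnull >= wobs - 1e-12))
}

upper_vec <- function(d) {
  d <- as.matrix(d)
  t(d)[lower.tri(d)]
}

rank_to_matrix <- function(d) {
  d <- as.matrix(d)
  r <- rank(upper_vec(d), ties.method = "average")
  n <- nrow(d)
  m <- matrix(0, n, n)
  tm <- m
  tm[lower.tri(tm)] <- r
  t(tm) + tm
}

random_dist <- function(n, seed, dim = 3) {
  set.seed(seed)
  p <- matrix(rnorm(n * dim), n, dim)
  dist_matrix(as.matrix(dist(p)))
}

# small blueprint builders used by the morphometrics tests
single_cylinder_blueprint <- function(radius, length, seed = 1) {
  generate_colony_blueprint(list(mean_radius = radius,
                                 mean_branch_length = length,
                                 branch_angle = 45, n_generations = 1),
                            seed = seed)
}

y_blueprint <- function(angle = 60, radius = 2.5, length = 25, seed = 2) {
  generate_colony_blueprint(list(mean_radius = radius,
                                 mean_branch_length = length,
                                 branch_angle = angle, n_generations = 2),
                            seed = seed)
}
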