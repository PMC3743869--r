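#' Medial-axis curve skeleton of a branching volume
#'
#' Reduces a binary colony volume to a one-voxel-wide centerline graph with
#' an inscribed-sphere radius at every centerline point. The volume is first
#' reduced to its largest 26-connected component and resampled (trilinear,
#' 0.5 threshold) to isotropic voxels at the finest axis pitch (3D thinning
#' assumes isotropy; CT stacks are strongly anisotropic). Directional
#' homotopic thinning with curve-endpoint preservation reduces the object
#' to a one-voxel curve; the spanning tree of the skeleton voxel graph is
#' decomposed into significant centerline paths (terminal paths shorter
#' than `prune_length` — corallite-scale surface spurs — are dropped);
#' junction clusters are contracted, crease-ridge artifact branches are
#' filtered, and tip ends are trimmed back by one local radius to the
#' medial-axis endpoint. Radii come from the anisotropic Euclidean distance
#' transform, hill-climbed to the local distance ridge.
#'
#' @param volume a [voxel_volume()] with at least one foreground voxel.
#' @param prune_length minimum terminal branch arc length (mm) to keep;
#'   `NULL` (default) uses twice the median inscribed diameter along the
#'   skeleton.
#' @param pitch isotropic resampling pitch in mm; default `min(spacing)`.
#' @return a `medial_skeleton`: list with `nodes` (data frame: id, kind
#'   tip/junction/basal, position), `branches` (each with proximal/distal
#'   node ids, ordered centerline points in mm, per-point inscribed radii in
#'   mm, arc length), `pitch`, and `tree_like` flag (FALSE if the pruned
#'   skeleton still contained a genuine cycle).
#' @export
skeletonize <- function(volume, prune_length = NULL, pitch = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!any(volume$occ)) stop("volume has no foreground voxels")
  vol <- largest_component(volume)
  iso <- resample_isotropic(vol, pitch)
  h <- iso$spacing[1]
  d <- dim(iso$occ)
  edt <- edt3d_cpp(as.logical(iso$occ), as.integer(d), as.numeric(iso$spacing))
  skel <- thin3d_directional_cpp(as.logical(iso$occ), as.integer(d))

  lin <- which(skel)
  if (length(lin) == 0) stop("thinning removed the whole object")
  coords <- arrayInd(lin, d)
  pos <- voxel_to_point(iso, coords)
  # Inscribed radius at each centerline point: hill-climb the distance map
  # to its local maximum. A lattice curve sits a little off the true medial
  # axis (and can wander more where thinning resolves wide plateaus), which
  # makes the pointwise distance value under-read the branch radius; the
  # nearest distance-ridge value is the honest inscribed radius.
  edt_arr <- array(edt, dim = d)
  # raw radius: neighbourhood max only -- reflects the local tube thickness
  # and is what the artifact filters compare against (hill-climbed values
  # lean into a neighbouring thick branch and would mask thin spurs)
  rad_raw <- vapply(seq_along(lin), function(k) {
    i <- coords[k, ]
    lo <- pmax(i - 1L, 1L)
    hi <- pmin(i + 1L, d)
    max(edt_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  }, 0)
  rad <- vapply(seq_along(lin), function(k) {
    cur <- coords[k, ]
    val <- edt_arr[cur[1], cur[2], cur[3]]
    for (step in seq_len(100)) {
      lo <- pmax(cur - 1L, 1L)
      hi <- pmin(cur + 1L, d)
      nb <- edt_arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      mx <- max(nb)
      if (mx <= val + 1e-12) break
      w <- which(nb == mx, arr.ind = TRUE)[1, ]
      cur <- lo + as.integer(w) - 1L
      val <- mx
    }
    val
  }, 0)

  g <- voxel_graph(lin, d, h)
  if (is.null(prune_length)) prune_length <- 2 * stats::median(2 * rad)

  tree_like <- TRUE
  if (length(g$edges)) {
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    igraph::E(ig)$weight <- g$wt
    if (igraph::vcount(ig) < length(lin)) {
      ig <- igraph::add_vertices(ig, length(lin) - igraph::vcount(ig))
    }
    mst <- igraph::mst(ig)
    # genuine loops show up as non-tree edges closing long cycles; short
    # chords are just 26-neighbourhood redundancy
    extra <- igraph::difference(ig, mst)
    if (igraph::ecount(extra) > 0) {
      # a non-tree edge closing a path much longer than the branch diameter
      # is a genuine loop (anastomosis); short chords are lattice redundancy
      loop_scale <- max(6 * stats::median(2 * rad), 12 * h)
      el <- igraph::as_edgelist(extra, names = FALSE)
      vv <- unique(el[, 1])
      dd <- igraph::distances(mst, v = vv)
      for (r in seq_len(nrow(el))) {
        len_mm <- dd[match(el[r, 1], vv), el[r, 2]]
        if (is.finite(len_mm) && len_mm > loop_scale) tree_like <- FALSE
      }
    }
    adj <- lapply(igraph::as_adj_list(mst), as.integer)
    keep <- accept_significant_paths(mst, prune_length)
  } else {
    adj <- rep(list(integer(0)), length(lin))
    keep <- rep(TRUE, length(lin))
  }
  if (!tree_like) {
    warning("skeleton contains cycles: colony is not tree-like; ",
            "cycles were broken along the minimum spanning tree")
  }

  sk <- build_branches(adj, pos, rad, rad_raw, keep)
  sk <- contract_short_junction_links(sk)
  sk <- splice_degree2_nodes(sk)
  sk <- filter_thin_spurs(sk)
  sk <- filter_overlapping_spurs(sk)
  sk <- contract_short_junction_links(sk)
  sk <- splice_degree2_nodes(sk)
  sk <- trim_tip_overshoot(sk)
  total_arc <- sum(vapply(sk$branches, `[[`, 0, "arc_length"))
  if (length(sk$branches) > 0 && total_arc < prune_length) {
    # no elongation beyond the spur scale: treat as degenerate (e.g. a ball)
    sk$branches <- list()
    sk$nodes <- sk$nodes[0, ]
  }
  if (length(sk$branches) == 0) {
    warning("no branches after pruning: shape is degenerate ",
            "(no elongated structure at this prune length)")
  }
  sk$pitch <- h
  sk$tree_like <- tree_like
  sk$prune_length <- prune_length
  class(sk) <- "medial_skeleton"
  orient_skeleton(sk)
}

#' @export
print.medial_skeleton <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, c("basal", "junction", "tip")))
  cat(sprintf("Medial skeleton: %d branches, %d junctions, %d tips%s\n",
              length(x$branches), kinds[["junction"]], kinds[["tip"]],
              if (!x$tree_like) " [NOT tree-like]" else ""))
  invisible(x)
}

# 26-neighbourhood adjacency among skeleton voxels (linear indices `lin`
# into a volume of dims d); edge weights are physical step lengths.
voxel_graph <- function(lin, d, h) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  # half the offsets to avoid duplicate edges
  off <- off[off[, 1] > 0 | (off[, 1] == 0 & off[, 2] > 0) |
               (off[, 1] == 0 & off[, 2] == 0 & off[, 3] > 0), , drop = FALSE]
  coords <- arrayInd(lin, d)
  edges <- list()
  wts <- list()
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nlin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    hit <- match(nlin, lin)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    if (length(src)) {
      edges[[length(edges) + 1]] <- cbind(src, dst)
      wts[[length(wts) + 1]] <- rep(h * sqrt(sum(off[r, ]^2)), length(src))
    }
  }
  list(edges = if (length(edges)) do.call(rbind, edges) else
         matrix(0L, 0, 2),
       wt = unlist(wts))
}

# Decompose the spanning tree into significant centerline paths: accept the
# tree diameter path, then iteratively the farthest remaining leaf's path to
# the accepted set, until every unaccepted voxel lies within prune_length
# (arc, mm) of the accepted skeleton. Unlike iterative leaf clipping, this
# cannot nibble a long branch to death through locally thick (bloblike)
# skeleton regions: a real branch keeps its full path length to the backbone
# no matter how messy the voxels around its base are.
accept_significant_paths <- function(mst, prune_length) {
  n <- igraph::vcount(mst)
  if (n <= 2) return(rep(TRUE, n))
  comp <- igraph::components(mst)
  main <- which(comp$membership == which.max(comp$csize))
  d1 <- igraph::distances(mst, v = main[1])[1, ]
  u <- main[which.max(d1[main])]
  du <- igraph::distances(mst, v = u)[1, ]
  w <- main[which.max(du[main])]
  path <- igraph::shortest_paths(mst, from = u, to = w)$vpath[[1]]
  accepted <- rep(FALSE, n)
  accepted[as.integer(path)] <- TRUE
  repeat {
    acc <- which(accepted)
    dd <- igraph::distances(mst, v = acc)
    dmin <- apply(dd, 2, min)
    cand <- which(!accepted & is.finite(dmin) & dmin > prune_length)
    if (!length(cand)) break
    far <- cand[which.max(dmin[cand])]
    target <- acc[which.min(dd[, far])]
    p <- igraph::shortest_paths(mst, from = far, to = target)$vpath[[1]]
    accepted[as.integer(p)] <- TRUE
  }
  accepted
}

# extract node clusters and branch paths from the pruned voxel tree
build_branches <- function(adj, pos, rad, rad_raw, keep) {
  n <- length(adj)
  dg <- vapply(seq_len(n), function(i) {
    if (!keep[i]) 0L else sum(keep[adj[[i]]])
  }, integer(1))
  is_junc <- keep & dg >= 3L
  is_tip <- keep & dg == 1L

  # junction clusters: connected components of adjacent junction voxels
  cluster <- rep(0L, n)
  ncl <- 0L
  for (s in which(is_junc)) {
    if (cluster[s]) next
    ncl <- ncl + 1L
    stack <- s
    cluster[s] <- ncl
    while (length(stack)) {
      c0 <- stack[[1]]
      stack <- stack[-1]
      for (nb in adj[[c0]]) {
        if (is_junc[nb] && !cluster[nb]) {
          cluster[nb] <- ncl
          stack <- c(stack, nb)
        }
      }
    }
  }
  node_of <- rep(NA_integer_, n)
  nodes <- list()
  for (cl in seq_len(ncl)) {
    vox <- which(cluster == cl)
    nodes[[cl]] <- list(kind = "junction",
                        pos = colMeans(pos[vox, , drop = FALSE]))
    node_of[vox] <- cl
  }
  nid <- ncl
  for (tp in which(is_tip)) {
    nid <- nid + 1L
    nodes[[nid]] <- list(kind = "tip", pos = pos[tp, ])
    node_of[tp] <- nid
  }
  # isolated voxels (degenerate shapes) become no branches at all

  branches <- list()
  seen <- new.env(hash = TRUE)
  for (v in which(is_junc | is_tip)) {
    for (u in adj[[v]]) {
      if (!keep[u]) next
      if (!is.na(node_of[u]) && node_of[u] == node_of[v]) next # intra-cluster
      key <- paste0(v, "_", u)
      if (!is.null(seen[[key]])) next
      path <- c(v, u)
      prev <- v
      cur <- u
      while (is.na(node_of[cur])) {
        nxt <- setdiff(adj[[cur]][keep[adj[[cur]]]], prev)
        if (length(nxt) != 1L) break
        path <- c(path, nxt)
        prev <- cur
        cur <- nxt
      }
      endv <- path[length(path)]
      seen[[key]] <- TRUE
      seen[[paste0(endv, "_", path[length(path) - 1L])]] <- TRUE
      branches[[length(branches) + 1L]] <- list(
        node_a = node_of[v], node_b = node_of[endv],
        points = pos[path, , drop = FALSE],
        radii = rad[path],
        radii_raw = rad_raw[path],
        arc_length = sum(sqrt(rowSums(diff(pos[path, , drop = FALSE])^2))))
    }
  }
  node_df <- if (length(nodes)) {
    data.frame(id = seq_along(nodes),
               kind = vapply(nodes, `[[`, "", "kind"),
               x = vapply(nodes, function(nd) nd$pos[1], 0),
               y = vapply(nodes, function(nd) nd$pos[2], 0),
               z = vapply(nodes, function(nd) nd$pos[3], 0))
  } else {
    data.frame(id = integer(0), kind = character(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  }
  list(nodes = node_df, branches = branches)
}

# A junction-junction branch shorter than the local branch diameter lies
# inside one thick junction region: merge its endpoints into a single
# junction node (centroid) and drop the connector.
contract_short_junction_links <- function(sk) {
  repeat {
    if (length(sk$branches) < 2) return(sk)
    kinds <- sk$nodes$kind
    short <- which(vapply(sk$branches, function(b) {
      kinds[b$node_a] == "junction" && kinds[b$node_b] == "junction" &&
        b$node_a != b$node_b &&
        b$arc_length < mean(2 * b$radii)
    }, TRUE))
    if (!length(short)) return(sk)
    b <- sk$branches[[short[1]]]
    a <- b$node_a
    z <- b$node_b
    sk$nodes[a, c("x", "y", "z")] <-
      (sk$nodes[a, c("x", "y", "z")] + sk$nodes[z, c("x", "y", "z")]) / 2
    sk$branches <- sk$branches[-short[1]]
    for (i in seq_along(sk$branches)) {
      if (sk$branches[[i]]$node_a == z) sk$branches[[i]]$node_a <- a
      if (sk$branches[[i]]$node_b == z) sk$branches[[i]]$node_b <- a
    }
    # node z stays in the table but is no longer referenced; mark it
    sk$nodes$kind[z] <- "merged"
  }
}

# Where two branch surfaces meet, the crease forms a sharp ridge whose own
# medial curve survives thinning as a long, very thin terminal branch; such
# artifacts have an inscribed diameter far below any real branch of the
# colony. Iteratively drop terminal branches thinner than `frac` times the
# median branch diameter.
filter_thin_spurs <- function(sk, frac = 0.6) {
  repeat {
    if (length(sk$branches) < 2) return(sk)
    ends <- cbind(vapply(sk$branches, `[[`, 0L, "node_a"),
                  vapply(sk$branches, `[[`, 0L, "node_b"))
    diam <- vapply(sk$branches, function(b) stats::median(2 * b$radii_raw), 0)
    med <- stats::median(diam)
    incid <- tabulate(ends, nbins = nrow(sk$nodes))
    is_terminal <- vapply(seq_along(sk$branches), function(i) {
      any(sk$nodes$kind[ends[i, ]] == "tip" & incid[ends[i, ]] == 1L)
    }, TRUE)
    drop <- which(is_terminal & diam < frac * med)
    if (!length(drop)) return(sk)
    i <- drop[which.min(diam[drop])]
    tipn <- ends[i, sk$nodes$kind[ends[i, ]] == "tip" & incid[ends[i, ]] == 1L]
    sk$nodes$kind[tipn[1]] <- "merged"
    sk$branches <- sk$branches[-i]
    sk <- splice_degree2_nodes(sk)
  }
}

# A crease-ridge artifact (see filter_thin_spurs) can be almost as thick as
# a real branch when its inscribed spheres lean into the neighbouring tube.
# Its giveaway is geometric: most of its centerline lies *inside* another
# branch's tube. Real branches only do that over the short stretch where
# they emerge from their parent at a junction.
filter_overlapping_spurs <- function(sk, prop = 0.6, rad_frac = 0.8) {
  repeat {
    if (length(sk$branches) < 2) return(sk)
    ends <- cbind(vapply(sk$branches, `[[`, 0L, "node_a"),
                  vapply(sk$branches, `[[`, 0L, "node_b"))
    incid <- tabulate(ends, nbins = nrow(sk$nodes))
    overlap <- rep(0, length(sk$branches))
    for (i in seq_along(sk$branches)) {
      terminal <- any(sk$nodes$kind[ends[i, ]] == "tip" &
                        incid[ends[i, ]] == 1L)
      if (!terminal) next
      p <- sk$branches[[i]]$points
      inside <- logical(nrow(p))
      for (j in seq_along(sk$branches)) {
        if (j == i) next
        q <- sk$branches[[j]]$points
        rq <- sk$branches[[j]]$radii_raw
        for (k in which(!inside)) {
          d2 <- rowSums(sweep(q, 2, p[k, ])^2)
          kk <- which.min(d2)
          if (sqrt(d2[kk]) < rad_frac * rq[kk]) inside[k] <- TRUE
        }
      }
      overlap[i] <- mean(inside)
    }
    worst <- which.max(overlap)
    if (overlap[worst] <= prop) return(sk)
    tipn <- ends[worst, sk$nodes$kind[ends[worst, ]] == "tip" &
                   incid[ends[worst, ]] == 1L]
    sk$nodes$kind[tipn[1]] <- "merged"
    sk$branches <- sk$branches[-worst]
    sk <- splice_degree2_nodes(sk)
  }
}

# a junction left with exactly two incident branches is no junction at all:
# splice the two branches into one continuous centerline
splice_degree2_nodes <- function(sk) {
  repeat {
    if (length(sk$branches) < 2) return(sk)
    ends <- cbind(vapply(sk$branches, `[[`, 0L, "node_a"),
                  vapply(sk$branches, `[[`, 0L, "node_b"))
    cand <- which(sk$nodes$kind == "junction" &
                    vapply(sk$nodes$id, function(v) {
                      sum(ends == v) == 2L
                    }, TRUE))
    if (!length(cand)) return(sk)
    v <- sk$nodes$id[cand[1]]
    bi <- which(ends[, 1] == v | ends[, 2] == v)
    if (length(bi) != 2L || bi[1] == bi[2]) {
      sk$nodes$kind[cand[1]] <- "merged"
      next
    }
    flip <- function(b) {
      b$points <- b$points[rev(seq_len(nrow(b$points))), , drop = FALSE]
      b$radii <- rev(b$radii)
      b$radii_raw <- rev(b$radii_raw)
      tmp <- b$node_a
      b$node_a <- b$node_b
      b$node_b <- tmp
      b
    }
    b1 <- sk$branches[[bi[1]]]
    b2 <- sk$branches[[bi[2]]]
    if (b1$node_b != v) b1 <- flip(b1)
    if (b2$node_a != v) b2 <- flip(b2)
    merged <- list(node_a = b1$node_a, node_b = b2$node_b,
                   points = rbind(b1$points, b2$points[-1, , drop = FALSE]),
                   radii = c(b1$radii, b2$radii[-1]),
                   radii_raw = c(b1$radii_raw, b2$radii_raw[-1]),
                   arc_length = b1$arc_length + b2$arc_length)
    sk$branches[[bi[1]]] <- merged
    sk$branches <- sk$branches[-bi[2]]
    sk$nodes$kind[cand[1]] <- "merged"
  }
}

# Homotopic thinning lets the curve run all the way into a branch's rounded
# end cap, where the inscribed radius collapses; the medial axis of a tube
# ends one radius short of the surface. Trim each tip-terminated branch end
# back until its arc distance from the (old) endpoint reaches the local
# inscribed radius.
trim_tip_overshoot <- function(sk) {
  if (length(sk$branches) == 0) return(sk)
  trim_end <- function(b) {
    np <- nrow(b$points)
    if (np < 3) return(b)
    arc_to_end <- rev(c(0, cumsum(sqrt(rowSums(diff(
      b$points[rev(seq_len(np)), , drop = FALSE])^2)))))
    # reference radius from the branch interior: the overshoot region's own
    # radii are exactly the depressed values we are cutting away
    r_ref <- as.numeric(stats::quantile(b$radii, 0.75))
    cut <- which(arc_to_end >= r_ref)
    last <- if (length(cut)) max(cut) else np
    last <- max(last, 2L)
    b$points <- b$points[seq_len(last), , drop = FALSE]
    b$radii <- b$radii[seq_len(last)]
    b$radii_raw <- b$radii_raw[seq_len(last)]
    b$arc_length <- sum(sqrt(rowSums(diff(b$points)^2)))
    b
  }
  flip <- function(b) {
    b$points <- b$points[rev(seq_len(nrow(b$points))), , drop = FALSE]
    b$radii <- rev(b$radii)
    b$radii_raw <- rev(b$radii_raw)
    tmp <- b$node_a
    b$node_a <- b$node_b
    b$node_b <- tmp
    b
  }
  for (i in seq_along(sk$branches)) {
    b <- sk$branches[[i]]
    if (sk$nodes$kind[b$node_b] == "tip") {
      b <- trim_end(b)
      sk$nodes[b$node_b, c("x", "y", "z")] <-
        as.list(b$points[nrow(b$points), ])
    }
    if (sk$nodes$kind[b$node_a] == "tip") {
      b <- flip(trim_end(flip(b)))
      sk$nodes[b$node_a, c("x", "y", "z")] <- as.list(b$points[1, ])
    }
    sk$branches[[i]] <- b
  }
  sk
}

# root the skeleton at the lowest-y tip (growth along +y) and orient every
# branch proximal -> distal by breadth-first search from the basal node
orient_skeleton <- function(sk) {
  if (length(sk$branches) == 0 || nrow(sk$nodes) == 0) return(sk)
  tips <- which(sk$nodes$kind == "tip")
  basal <- if (length(tips)) tips[which.min(sk$nodes$y[tips])] else 1L
  sk$nodes$kind[basal] <- "basal"
  nb <- length(sk$branches)
  bnodes <- cbind(vapply(sk$branches, `[[`, 0L, "node_a"),
                  vapply(sk$branches, `[[`, 0L, "node_b"))
  visited_n <- rep(FALSE, nrow(sk$nodes))
  visited_b <- rep(FALSE, nb)
  queue <- basal
  visited_n[basal] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (bi in which(!visited_b)) {
      if (bnodes[bi, 1] == v || bnodes[bi, 2] == v) {
        visited_b[bi] <- TRUE
        if (bnodes[bi, 2] == v) { # flip so node_a is proximal
          sk$branches[[bi]]$points <-
            sk$branches[[bi]]$points[rev(seq_len(nrow(sk$branches[[bi]]$points))), , drop = FALSE]
          sk$branches[[bi]]$radii <- rev(sk$branches[[bi]]$radii)
          sk$branches[[bi]]$radii_raw <- rev(sk$branches[[bi]]$radii_raw)
          tmp <- sk$branches[[bi]]$node_a
          sk$branches[[bi]]$node_a <- sk$branches[[bi]]$node_b
          sk$branches[[bi]]$node_b <- tmp
          bnodes[bi, ] <- bnodes[bi, 2:1]
        }
        w <- bnodes[bi, 2]
        if (!visited_n[w]) {
          visited_n[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  sk
}
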