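#' Average-linkage (UPGMA) dendrogram
#'
#' Agglomerative clustering with unweighted average linkage: at each step the
#' pair of clusters with the smallest mean between-cluster distance merges,
#' at a node height of half that distance (so the dendrogram is ultrametric
#' and the cophenetic distance between two leaves equals the average
#' distance between their clusters at the merge). Ties are broken by the
#' lexicographic order of the merged clusters' member labels, so results are
#' platform-independent.
#'
#' @param d a [dist_matrix()] (or coercible matrix / `dist`).
#' @param method `"unweighted"` (UPGMA, default; cluster-size-weighted
#'   update) or `"weighted"` (WPGMA).
#' @return an object of class `upgma_tree`: `merge` and `order` in
#'   [stats::hclust()] convention, `height` (node depths = half the merge
#'   distance), `labels`.
#' @export
average_linkage_tree <- function(d, method = c("unweighted", "weighted")) {
  method <- match.arg(method)
  d <- dist_matrix(d)
  if (anyNA(d) || any(d < 0)) stop("distances must be finite and nonnegative")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2) stop("need at least 2 labels")
  D <- unclass(d)
  active <- rep(TRUE, n)
  members <- as.list(seq_len(n))
  code <- -seq_len(n) # hclust convention: negative = singleton
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    act <- which(active)
    best <- NULL
    bestd <- Inf
    bestkey <- ""
    for (ii in seq_along(act)[-length(act)]) {
      for (jj in (ii + 1):length(act)) {
        i <- act[ii]; j <- act[jj]
        dij <- D[i, j]
        key <- paste(sort(labels[c(members[[i]], members[[j]])]),
                     collapse = "\r")
        if (dij < bestd - 1e-15 ||
            (abs(dij - bestd) <= 1e-15 && key < bestkey)) {
          bestd <- dij
          best <- c(i, j)
          bestkey <- key
        }
      }
    }
    i <- best[1]; j <- best[2]
    # deterministic child order: cluster with the smaller member label first
    li <- min(labels[members[[i]]])
    lj <- min(labels[members[[j]]])
    merge[step, ] <- if (li < lj) c(code[i], code[j]) else c(code[j], code[i])
    height[step] <- bestd / 2
    for (k in which(active)) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- if (method == "unweighted") {
        (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
      } else {
        (D[i, k] + D[j, k]) / 2
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    code[i] <- step
    active[j] <- FALSE
  }
  out <- list(merge = merge, height = height, labels = labels,
              order = dendro_order(merge))
  class(out) <- "upgma_tree"
  out
}

dendro_order <- function(merge) {
  walk <- function(code) {
    if (code < 0) return(-code)
    c(walk(merge[code, 1]), walk(merge[code, 2]))
  }
  walk(nrow(merge))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Cophenetic distances of a UPGMA dendrogram
#'
#' The cophenetic distance between two leaves is the average between-cluster
#' distance at which they first merge (twice the node height).
#'
#' @param tree an `upgma_tree`.
#' @return a [dist_matrix()].
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  m <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  leafsets <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    side <- lapply(tree$merge[step, ], function(code) {
      if (code < 0) -code else leafsets[[code]]
    })
    for (a in side[[1]]) {
      m[a, side[[2]]] <- m[side[[2]], a] <- 2 * tree$height[step]
    }
    leafsets[[step]] <- c(side[[1]], side[[2]])
  }
  dist_matrix(m)
}

#' Convert a UPGMA dendrogram to an ape phylogeny
#'
#' Branch lengths are differences of node heights, so leaf-to-root path
#' lengths all equal the root height (ultrametric).
#'
#' @param tree an `upgma_tree`.
#' @return a `phylo` object.
#' @export
upgma_as_phylo <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  nwk <- function(code) {
    if (code < 0) {
      list(txt = tree$labels[-code], h = 0)
    } else {
      l <- nwk(tree$merge[code, 1])
      r <- nwk(tree$merge[code, 2])
      h <- tree$height[code]
      list(txt = sprintf("(%s:%.10g,%s:%.10g)", l$txt, h - l$h,
                         r$txt, h - r$h),
           h = h)
    }
  }
  ape::read.tree(text = paste0(nwk(nrow(tree$merge))$txt, ";"))
}

#' Topological (unit-branch-length cophenetic) distances between leaves
#'
#' Entry (i, j) is the number of edges on the unique path between leaves i
#' and j, ignoring stored branch lengths — the cophenetic distance in the
#' tree with all branch lengths set to 1. The tree is treated as rooted as
#' given; the root is an ordinary path vertex.
#'
#' @param tree a `phylo` object (or an `upgma_tree`).
#' @return a [dist_matrix()] of integer edge counts.
#' @export
topological_distances <- function(tree) {
  if (inherits(tree, "upgma_tree")) tree <- upgma_as_phylo(tree)
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  if (anyDuplicated(labels)) stop("duplicate leaf labels")
  n <- length(labels)
  if (n < 2) stop("tree must have at least 2 leaves")
  nnode <- n + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- rep(NA_integer_, nnode)
  node_depth <- function(v) {
    if (!is.na(depth[v])) return(depth[v])
    d <- if (is.na(parent[v])) 0L else node_depth(parent[v]) + 1L
    depth[v] <<- d
    d
  }
  for (v in seq_len(nnode)) node_depth(v)
  ancestors <- lapply(seq_len(n), function(v) {
    path <- v
    while (!is.na(parent[path[length(path)]])) {
      path <- c(path, parent[path[length(path)]])
    }
    path
  })
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      common <- intersect(ancestors[[i]], ancestors[[j]])
      mrca <- common[which.max(depth[common])]
      m[i, j] <- m[j, i] <- depth[i] + depth[j] - 2L * depth[mrca]
    }
  }
  dist_matrix(m)
}

#' Collapse allele-level distances to sample level
#'
#' Sample-level entry = mean of the allele-pair entries between the two
#' samples' alleles; a homozygote's single allele is duplicated, i.e.
#' weighted as two identical alleles, so all comparisons average four
#' terms. Diagonal is 0.
#'
#' @param d distance matrix over allele labels.
#' @param genotype_map named list: sample id -> character vector of that
#'   sample's allele labels (1 or 2).
#' @return a [dist_matrix()] over sample ids.
#' @export
collapse_allele_distances <- function(d, genotype_map) {
  d <- as.matrix(d)
  allele_labels <- rownames(d)
  mapped <- unlist(genotype_map, use.names = FALSE)
  if (anyDuplicated(mapped)) stop("an allele label maps to several samples")
  unmapped <- setdiff(allele_labels, mapped)
  if (length(unmapped)) {
    stop("allele label(s) not mapped to any sample: ",
         paste(unmapped, collapse = ", "))
  }
  missing <- setdiff(mapped, allele_labels)
  if (length(missing)) {
    stop("mapped allele label(s) absent from the matrix: ",
         paste(missing, collapse = ", "))
  }
  samples <- names(genotype_map)
  ns <- length(samples)
  out <- matrix(0, ns, ns, dimnames = list(samples, samples))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      ai <- rep(genotype_map[[i]], length.out = 2)
      aj <- rep(genotype_map[[j]], length.out = 2)
      out[i, j] <- out[j, i] <- mean(d[ai, aj])
    }
  }
  dist_matrix(out)
}

#' Read and write Newick trees
#'
#' Thin validating wrappers for ingesting externally inferred trees:
#' parse errors (unbalanced parentheses, trailing garbage) and duplicate
#' leaf labels are turned into informative errors; topology, labels and
#' branch lengths round-trip to printed precision.
#'
#' @param text a Newick string, or a file path when `file = TRUE`.
#' @param file read `text` as a path.
#' @return [read_newick()] returns a `phylo`; [write_newick()] a string
#'   (invisibly, after writing when `path` is given).
#' @rdname newick-io
#' @export
read_newick <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  depth <- cumsum(vapply(strsplit(text, "")[[1]], function(ch) {
    if (ch == "(") 1L else if (ch == ")") -1L else 0L
  }, 0L))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    bad <- if (any(depth < 0)) which(depth < 0)[1] else length(depth)
    stop("unbalanced parentheses in Newick string near position ", bad)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("failed to parse Newick string")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  }
  tr
}

#' @param tree a `phylo` or `upgma_tree`.
#' @param path optional output file.
#' @rdname newick-io
#' @export
write_newick <- function(tree, path = NULL) {
  if (inherits(tree, "upgma_tree")) tree <- upgma_as_phylo(tree)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
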