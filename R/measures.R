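#' Measure branches of a medial skeleton
#'
#' Computes the seven branch-level measures from an oriented skeleton:
#' \describe{
#'   \item{da}{inscribed diameter (mm) at the proximal end of the branch —
#'     the thickness at the beginning of the branching point.}
#'   \item{db}{inscribed diameter (mm) one local diameter distal to the
#'     junction along the branch — the thickness after branching.}
#'   \item{dc}{inscribed diameter (mm) at the tip point (tip branches only).}
#'   \item{b_angle}{angle (degrees) between the medial-axis directions of the
#'     two sibling branches emanating from the same junction.}
#'   \item{g_angle}{angle (degrees) between the branch direction and the
#'     positive y-axis (the growth direction).}
#'   \item{rb}{branching rate: centerline arc length (mm) of the branch from
#'     its origin to its next split (or tip).}
#'   \item{br_spacing}{branch spacing: distance (mm) from the branch tip to
#'     the nearest centerline point of a different branch (tip branches
#'     only).}
#' }
#' Branch directions are total-least-squares line fits to the centerline
#' (first principal component), oriented proximal to distal; a configurable
#' alternative uses the endpoint-to-endpoint chord.
#'
#' @param skeleton a `medial_skeleton` from [skeletonize()].
#' @param volume the source [voxel_volume()] (optional; radii recorded along
#'   the skeleton centerline are used directly).
#' @param direction `"tls"` (default) or `"chord"`: branch axis estimator.
#' @return data frame with one row per branch: `branch`, `is_tip`, `da`,
#'   `db`, `dc`, `b_angle`, `g_angle`, `rb`, `br_spacing`, `diameter` (mean
#'   interior inscribed diameter used for aggregation) and `n_points`.
#' @export
measure_branches <- function(skeleton, volume = NULL,
                             direction = c("tls", "chord")) {
  stopifnot(inherits(skeleton, "medial_skeleton"))
  direction <- match.arg(direction)
  brs <- skeleton$branches
  ok <- vapply(brs, function(b) nrow(b$points) >= 2, TRUE)
  if (any(!ok)) {
    warning(sum(!ok), " branch(es) with < 2 centerline points excluded")
    brs <- brs[ok]
  }
  if (length(brs) == 0) {
    return(data.frame(branch = integer(0), is_tip = logical(0),
                      da = numeric(0), db = numeric(0), dc = numeric(0),
                      b_angle = numeric(0), g_angle = numeric(0),
                      rb = numeric(0), br_spacing = numeric(0),
                      diameter = numeric(0), n_points = integer(0)))
  }
  nodes <- skeleton$nodes
  dirs <- t(vapply(brs, branch_direction, numeric(3), method = direction))
  prox <- vapply(brs, `[[`, 0L, "node_a")
  dist_node <- vapply(brs, `[[`, 0L, "node_b")
  is_tip <- nodes$kind[dist_node] == "tip"

  n <- length(brs)
  da <- db <- dc <- b_angle <- g_angle <- rb <- br_spacing <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    b <- brs[[i]]
    arc <- c(0, cumsum(sqrt(rowSums(diff(b$points)^2))))
    rb[i] <- arc[length(arc)]
    da[i] <- 2 * b$radii[1]
    off <- which(arc >= da[i])
    db[i] <- 2 * b$radii[if (length(off)) off[1] else length(b$radii)]
    if (is_tip[i]) dc[i] <- 2 * b$radii[length(b$radii)]
    g_angle[i] <- angle_between(dirs[i, ], c(0, 1, 0))
    # interior mean diameter, excluding a half-diameter margin at each end
    marg <- mean(2 * b$radii) / 2
    interior <- arc > marg & arc < rb[i] - marg
    if (!any(interior)) interior <- rep(TRUE, length(arc))
    diam_i <- mean(2 * b$radii[interior])
    brs[[i]]$.diameter <- diam_i
  }
  diameter <- vapply(brs, `[[`, 0, ".diameter")

  # sibling angles at each junction: children of a junction are branches
  # whose proximal node is that junction
  for (j in which(nodes$kind == "junction")) {
    kids <- which(prox == j)
    if (length(kids) >= 2) {
      for (k in kids) {
        others <- setdiff(kids, k)
        b_angle[k] <- min(vapply(others, function(o) {
          angle_between(dirs[k, ], dirs[o, ])
        }, 0))
      }
    }
  }

  # branch spacing: tip to nearest centerline point of another branch
  if (n >= 2) {
    for (i in which(is_tip)) {
      tip <- brs[[i]]$points[nrow(brs[[i]]$points), ]
      dmin <- Inf
      for (j in seq_len(n)) {
        if (j == i) next
        dmin <- min(dmin, sqrt(min(rowSums(
          sweep(brs[[j]]$points, 2, tip)^2))))
      }
      br_spacing[i] <- dmin
    }
  }

  data.frame(branch = seq_len(n), is_tip = is_tip,
             da = da, db = db, dc = dc,
             b_angle = b_angle, g_angle = g_angle, rb = rb,
             br_spacing = br_spacing, diameter = diameter,
             n_points = vapply(brs, function(b) nrow(b$points), 0L))
}

branch_direction <- function(b, method = "tls") {
  p <- b$points
  chord <- p[nrow(p), ] - p[1, ]
  if (method == "chord" || nrow(p) == 2) {
    return(unitv(chord))
  }
  pc <- stats::prcomp(p, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  if (sum(v * chord) < 0) v <- -v
  unitv(v)
}

#' Aggregate branch measures into colony-level traits
#'
#' Reduces per-branch measures to the three colony traits used for the
#' morphological tree: branch thickness (mean representative diameter),
#' branch spacing (mean `br_spacing` over tip branches) and branch
#' length-to-thickness ratio (mean of `rb` over the branch's own diameter).
#'
#' @param measures data frame from [measure_branches()].
#' @param colony_id identifier stored with the result.
#' @param stat aggregation statistic, `"mean"` (default) or `"median"`.
#' @param diameter which per-branch diameter feeds the thickness trait:
#'   `"interior"` (mean interior inscribed diameter, default), `"da"`,
#'   `"db"` or `"dc"`.
#' @return a one-row data frame: `colony_id`, `thickness` (mm), `spacing`
#'   (mm), `length_thickness_ratio`.
#' @export
aggregate_features <- function(measures, colony_id,
                               stat = c("mean", "median"),
                               diameter = c("interior", "da", "db", "dc")) {
  stat <- match.arg(stat)
  diameter <- match.arg(diameter)
  if (nrow(measures) < 1) stop("no valid branches to aggregate")
  agg <- if (stat == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) stats::median(x, na.rm = TRUE)
  }
  d <- switch(diameter, interior = measures$diameter, da = measures$da,
              db = measures$db, dc = measures$dc)
  sp <- measures$br_spacing[measures$is_tip]
  sp <- sp[is.finite(sp)]
  if (length(sp) == 0) {
    stop("no tip branches with a defined spacing: spacing trait undefined")
  }
  data.frame(colony_id = colony_id,
             thickness = agg(d),
             spacing = agg(sp),
             length_thickness_ratio = agg(measures$rb / d))
}

#' Normalize colony trait columns
#'
#' Standardizes each trait to zero mean and unit standard deviation (sample,
#' n-1 convention) across colonies, the preparation step for Euclidean
#' morphological distances. Zero-variance traits are left at zero with a
#' warning.
#'
#' @param features data frame of rows from [aggregate_features()] (or any
#'   data frame with a `colony_id` column and numeric trait columns).
#' @return numeric matrix (colonies x traits) with colony ids as rownames;
#'   attribute `sd_convention` records the n-1 choice.
#' @export
normalize_features <- function(features) {
  if (nrow(features) < 2) stop("need at least 2 colonies to normalize")
  ids <- as.character(features$colony_id)
  m <- as.matrix(features[, setdiff(names(features), "colony_id"),
                          drop = FALSE])
  if (anyNA(m)) stop("features contain missing values")
  out <- m
  for (j in seq_len(ncol(m))) {
    s <- sd(m[, j])
    if (s == 0) {
      warning("trait '", colnames(m)[j], "' has zero variance; left at zero")
      out[, j] <- 0
    } else {
      out[, j] <- (m[, j] - mean(m[, j])) / s
    }
  }
  rownames(out) <- ids
  attr(out, "sd_convention") <- "sample (n-1)"
  out
}

#' Euclidean morphological distances between colonies
#'
#' Pairwise Euclidean distance in the space spanned by the (normalized)
#' colony traits.
#'
#' @param fm matrix from [normalize_features()] (colonies x traits).
#' @return a [dist_matrix()].
#' @export
morphological_distances <- function(fm) {
  if (anyNA(fm)) stop("feature matrix contains NaN/NA")
  dist_matrix(as.matrix(stats::dist(fm, method = "euclidean")))
}
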