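#' Generate a synthetic branching-colony blueprint
#'
#' Grows a strictly bifurcating 3D branching structure with a basal segment
#' along the growth axis (+y), recording exact per-segment geometry so that
#' every downstream morphometric has a known true value. At each bifurcation
#' the two children deflect symmetrically from the parent axis so the angle
#' between them equals `branch_angle` (plus jitter); the bifurcation plane's
#' azimuth advances by the golden angle between generations to spread
#' branches in 3D.
#'
#' This is a measurement test fixture, not a coral growth model: it emulates
#' the gross geometry CT scans of branching colonies present to the
#' morphometric pipeline (tubular branches, species-specific thickness,
#' spacing and length-to-thickness ratio), nothing more.
#'
#' @param species_params list with `mean_radius` (mm), `mean_branch_length`
#'   (mm), `branch_angle` (degrees, angle between sibling branches),
#'   `n_generations` (>= 1) and optional `spacing_target` (mm; enforces a
#'   minimum branch length so sibling tips end up at least this far apart).
#' @param seed integer seed; the blueprint is a pure function of
#'   (params, seed).
#' @param species_label label stored with the blueprint.
#' @param angle_jitter_sd s.d. (degrees) of normal jitter on each child's
#'   deflection; 0 gives exact angles.
#' @param length_cv,radius_cv lognormal coefficients of variation for segment
#'   length and radius; 0 gives exact values.
#' @param max_overlap maximum tolerated fraction of non-adjacent segment
#'   pairs whose centerlines come closer than the sum of their radii;
#'   exceeding it signals degenerate, self-intersecting geometry.
#' @return a `colony_blueprint`: data frame of segments (id, parent,
#'   generation, endpoints, radius, length, true angles) with the species
#'   label, growth axis and parameters as attributes.
#' @export
generate_colony_blueprint <- function(species_params, seed,
                                      species_label = "sp",
                                      angle_jitter_sd = 0,
                                      length_cv = 0,
                                      radius_cv = 0,
                                      max_overlap = 0.05) {
  p <- species_params
  req <- c("mean_radius", "mean_branch_length", "branch_angle",
           "n_generations")
  if (!all(req %in% names(p))) {
    stop("species_params must contain: ", paste(req, collapse = ", "))
  }
  if (p$mean_radius <= 0 || p$mean_branch_length <= 0 ||
      p$branch_angle <= 0) {
    stop("all species parameters must be positive")
  }
  if (p$n_generations < 1) stop("n_generations must be >= 1")
  growth_axis <- c(0, 1, 0)

  with_seed(seed, {
    draw_len <- function() {
      len <- p$mean_branch_length *
        if (length_cv > 0) exp(rnorm(1, 0, length_cv)) else 1
      if (!is.null(p$spacing_target)) {
        half <- (p$branch_angle / 2) * pi / 180
        len <- max(len, p$spacing_target / (2 * sin(half)))
      }
      len
    }
    draw_rad <- function() {
      p$mean_radius * if (radius_cv > 0) exp(rnorm(1, 0, radius_cv)) else 1
    }

    segs <- list()
    seg_row <- function(id, parent, gen, a, b, radius, b_angle, g_angle) {
      data.frame(id = id, parent = parent, generation = gen,
                 x0 = a[1], y0 = a[2], z0 = a[3],
                 x1 = b[1], y1 = b[2], z1 = b[3],
                 radius = radius, length = vnorm(b - a),
                 b_angle_true = b_angle, g_angle_true = g_angle)
    }

    basal_len <- draw_len()
    segs[[1]] <- seg_row(1L, 0L, 1L, c(0, 0, 0), c(0, basal_len, 0),
                         draw_rad(), NA_real_,
                         angle_between(growth_axis, growth_axis))
    frontier <- list(list(id = 1L, pos = c(0, basal_len, 0),
                          dir = growth_axis))
    next_id <- 2L
    golden <- 180 * (3 - sqrt(5)) # golden angle, degrees
    if (p$n_generations >= 2) {
      for (gen in 2:p$n_generations) {
        newfront <- list()
        for (fi in seq_along(frontier)) {
          fr <- frontier[[fi]]
          d <- fr$dir
          ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
          e1 <- unitv(c(d[2] * ref[3] - d[3] * ref[2],
                        d[3] * ref[1] - d[1] * ref[3],
                        d[1] * ref[2] - d[2] * ref[1]))
          e2 <- c(d[2] * e1[3] - d[3] * e1[2],
                  d[3] * e1[1] - d[1] * e1[3],
                  d[1] * e1[2] - d[2] * e1[1])
          phi <- ((gen - 2) * golden + (fi - 1) * 77 + runif(1, 0, 360)) *
            pi / 180
          w <- cos(phi) * e1 + sin(phi) * e2
          th <- (p$branch_angle / 2 +
                   if (angle_jitter_sd > 0) rnorm(2, 0, angle_jitter_sd)
                   else c(0, 0)) * pi / 180
          dirs <- list(unitv(cos(th[1]) * d + sin(th[1]) * w),
                       unitv(cos(th[2]) * d - sin(th[2]) * w))
          b_angle <- angle_between(dirs[[1]], dirs[[2]])
          for (ci in 1:2) {
            len <- draw_len()
            b <- fr$pos + len * dirs[[ci]]
            segs[[next_id]] <- seg_row(next_id, fr$id, gen, fr$pos, b,
                                       draw_rad(), b_angle,
                                       angle_between(dirs[[ci]], growth_axis))
            newfront[[length(newfront) + 1]] <-
              list(id = next_id, pos = b, dir = dirs[[ci]])
            next_id <- next_id + 1L
          }
        }
        frontier <- newfront
      }
    }
    bp <- do.call(rbind, segs)
    attr(bp, "species_label") <- species_label
    attr(bp, "growth_axis") <- growth_axis
    attr(bp, "params") <- p
    attr(bp, "seed") <- seed
    class(bp) <- c("colony_blueprint", "data.frame")
    frac <- blueprint_overlap_fraction(bp)
    if (frac > max_overlap) {
      stop(sprintf(paste0("degenerate geometry: %.0f%% of non-adjacent ",
                          "segment pairs self-intersect (max allowed %.0f%%)"),
                   100 * frac, 100 * max_overlap))
    }
    bp
  })
}

segment_endpoints <- function(bp) {
  list(a = as.matrix(bp[, c("x0", "y0", "z0")]),
       b = as.matrix(bp[, c("x1", "y1", "z1")]))
}

# Pairs of segments that legitimately touch: parent-child and siblings.
adjacent_pairs <- function(bp) {
  n <- nrow(bp)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    pa <- bp$parent[i]
    if (pa > 0) {
      adj[i, pa] <- adj[pa, i] <- TRUE
      sibs <- which(bp$parent == pa)
      adj[i, sibs] <- adj[sibs, i] <- TRUE
    }
  }
  diag(adj) <- TRUE
  adj
}

blueprint_overlap_fraction <- function(bp) {
  n <- nrow(bp)
  if (n < 2) return(0)
  ep <- segment_endpoints(bp)
  adj <- adjacent_pairs(bp)
  n_pairs <- 0L
  n_overlap <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (adj[i, j]) next
      n_pairs <- n_pairs + 1L
      dmin <- segment_to_segment(ep$a[i, ], ep$b[i, ], ep$a[j, ], ep$b[j, ])
      if (dmin < bp$radius[i] + bp$radius[j]) n_overlap <- n_overlap + 1L
    }
  }
  if (n_pairs == 0L) 0 else n_overlap / n_pairs
}

#' Ground-truth morphometrics of a blueprint
#'
#' Computes, from exact geometry, the quantities the measurement pipeline is
#' supposed to recover: per-segment diameters/lengths/angles, the colony
#' bifurcation count, and per-tip branch spacing (distance from each tip to
#' the nearest point on another, non-adjacent segment's centerline).
#'
#' @param bp a `colony_blueprint`.
#' @return list with `mean_diameter`, `mean_length`, `length_thickness_ratio`,
#'   `n_bifurcations`, `tip_spacing` (named by tip segment id) and
#'   `mean_tip_spacing`.
#' @export
blueprint_truth <- function(bp) {
  stopifnot(inherits(bp, "colony_blueprint"))
  ep <- segment_endpoints(bp)
  n <- nrow(bp)
  has_child <- bp$id %in% bp$parent
  tips <- which(!has_child)
  tip_sp <- rep(NA_real_, length(tips))
  names(tip_sp) <- bp$id[tips]
  if (n >= 2) {
    for (k in seq_along(tips)) {
      i <- tips[k]
      tip <- ep$b[i, ]
      dmin <- Inf
      for (j in seq_len(n)) {
        if (j == i) next
        dmin <- min(dmin, points_to_segment(tip, ep$a[j, ], ep$b[j, ]))
      }
      tip_sp[k] <- if (is.finite(dmin)) dmin else NA_real_
    }
  }
  list(mean_diameter = mean(2 * bp$radius),
       mean_length = mean(bp$length),
       length_thickness_ratio = mean(bp$length / (2 * bp$radius)),
       n_bifurcations = sum(has_child),
       tip_spacing = tip_sp,
       mean_tip_spacing = if (all(is.na(tip_sp))) NA_real_
                          else mean(tip_sp, na.rm = TRUE))
}

#' Rasterize a blueprint onto a voxel grid
#'
#' Marks a voxel foreground iff its center lies within a segment's radius of
#' that segment's centerline (zero-length segments are spheres). Geometry is
#' evaluated in physical mm, so anisotropic grids are supported directly. The
#' grid is padded with at least `pad` background voxels on every side.
#'
#' @param bp a `colony_blueprint`.
#' @param spacing mm/voxel along x, y, z.
#' @param pad background padding in voxels (>= 2).
#' @param crop optional list(min=, max=) mm box; voxels are restricted to it.
#' @return a [voxel_volume()].
#' @export
rasterize <- function(bp, spacing, pad = 2L, crop = NULL) {
  stopifnot(inherits(bp, "colony_blueprint"))
  if (nrow(bp) == 0) stop("empty blueprint")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("spacing must be three positive values")
  }
  pad <- max(2L, as.integer(pad))
  ep <- segment_endpoints(bp)
  lo <- pmin(apply(ep$a, 2, min), apply(ep$b, 2, min)) - max(bp$radius)
  hi <- pmax(apply(ep$a, 2, max), apply(ep$b, 2, max)) + max(bp$radius)
  if (!is.null(crop)) {
    if (any(lo > crop$max) || any(hi < crop$min)) {
      stop("blueprint lies entirely outside the requested crop box")
    }
    lo <- pmax(lo, crop$min)
    hi <- pmin(hi, crop$max)
  }
  origin <- lo - (pad - 0.5) * spacing
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 2L * pad
  occ <- array(FALSE, dim = dims)
  ax <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ay <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  az <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  for (i in seq_len(nrow(bp))) {
    a <- ep$a[i, ]; b <- ep$b[i, ]; r <- bp$radius[i]
    slo <- pmin(a, b) - r; shi <- pmax(a, b) + r
    ix <- which(ax >= slo[1] - spacing[1] & ax <= shi[1] + spacing[1])
    iy <- which(ay >= slo[2] - spacing[2] & ay <= shi[2] + spacing[2])
    iz <- which(az >= slo[3] - spacing[3] & az <= shi[3] + spacing[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    pts <- as.matrix(expand.grid(x = ax[ix], y = ay[iy], z = az[iz]))
    inside <- points_to_segment(pts, a, b) <= r
    if (any(inside)) {
      sub <- occ[ix, iy, iz, drop = FALSE]
      sub[array(inside, dim = c(length(ix), length(iy), length(iz)))] <- TRUE
      occ[ix, iy, iz] <- sub
    }
  }
  if (!any(occ)) stop("rasterization produced no foreground voxels")
  voxel_volume(occ, spacing, origin)
}
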