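#' @useDynLib phylomorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rnorm runif sd
NULL

# Run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

# angle between two vectors, degrees in [0, 180]
angle_between <- function(a, b) {
  ca <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# distance from points (n x 3) to a 3D segment a-b (zero-length = point)
points_to_segment <- function(p, a, b) {
  p <- rbind(p)
  ab <- b - a
  l2 <- sum(ab^2)
  if (l2 == 0) {
    return(sqrt(rowSums(sweep(p, 2, a)^2)))
  }
  tpar <- (sweep(p, 2, a) %*% ab) / l2
  tpar <- pmin(1, pmax(0, as.numeric(tpar)))
  closest <- outer(tpar, ab) + matrix(a, nrow(p), 3, byrow = TRUE)
  sqrt(rowSums((p - closest)^2))
}

# minimum distance between two 3D segments (sampled; exact enough for
# clearance checks at sub-voxel resolution)
segment_to_segment <- function(a0, a1, b0, b1, n = 25) {
  tt <- seq(0, 1, length.out = n)
  pa <- outer(tt, a1 - a0) + matrix(a0, n, 3, byrow = TRUE)
  min(vapply(seq_len(n), function(i) {
    min(points_to_segment(pa[i, , drop = FALSE], b0, b1))
  }, numeric(1)))
}
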