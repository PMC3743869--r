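#' Validate and construct a labeled distance matrix
#'
#' A distance matrix here is a plain numeric matrix with identical row and
#' column labels, zero diagonal, symmetry and nonnegative entries. It is the
#' common currency between the morphological, genetic and tree-derived stages.
#'
#' @param x square numeric matrix, a `dist` object, or a data frame coercible
#'   to one.
#' @param labels optional character vector of labels; defaults to existing
#'   dimnames.
#' @return a validated numeric matrix with dimnames, class `dist_matrix`.
#' @export
dist_matrix <- function(x, labels = NULL) {
  if (inherits(x, "dist")) x <- as.matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or a 'dist' object")
  }
  if (nrow(x) != ncol(x)) stop("distance matrix must be square")
  if (!is.null(labels)) {
    if (length(labels) != nrow(x)) stop("wrong number of labels")
    dimnames(x) <- list(labels, labels)
  }
  if (is.null(rownames(x))) {
    lab <- paste0("S", seq_len(nrow(x)))
    dimnames(x) <- list(lab, lab)
  }
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (!identical(rownames(x), colnames(x))) {
    stop("row and column labels differ")
  }
  if (anyNA(x)) stop("distance matrix contains NA")
  if (any(x < 0)) stop("distance matrix has negative entries")
  if (max(abs(x - t(x))) > 1e-8) stop("distance matrix is not symmetric")
  x <- (x + t(x)) / 2
  diag(x) <- 0
  class(x) <- c("dist_matrix", class(matrix()))
  x
}

#' Unroll the upper triangle of a distance matrix
#'
#' Returns the row-major upper-triangle (i < j) entries as a vector of length
#' n(n-1)/2. Matrices being compared must carry their labels in the same
#' order; `unroll()` refuses silently reordered inputs when a reference label
#' order is supplied.
#'
#' @param d square symmetric matrix.
#' @param labels optional reference label order; an error is raised if `d`'s
#'   labels differ from it (callers must align labels explicitly first).
#' @return numeric vector of the n(n-1)/2 off-diagonal values.
#' @export
unroll <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("matrix must be square")
  if (!is.null(labels) && !identical(rownames(d), labels)) {
    stop("label order mismatch: align matrix labels before unrolling")
  }
  # row-major upper triangle: (1,2), (1,3), ..., (1,n), (2,3), ...
  t(d)[lower.tri(d)]
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Distance matrix:", nrow(x), "objects\n")
  print(unclass(x), ...)
  invisible(x)
}

check_same_labels <- function(dlist) {
  labs <- lapply(dlist, rownames)
  for (i in seq_along(labs)[-1]) {
    if (!identical(labs[[i]], labs[[1]])) {
      stop("distance matrices must share the same labels in the same order")
    }
  }
  invisible(labs[[1]])
}

#' Read / write distance matrices
#'
#' CSV files carry the labels as header row and first column. PHYLIP square
#' format is the classic n-on-the-first-line, label-then-row layout.
#'
#' @param path file path.
#' @param d distance matrix.
#' @rdname dist-io
#' @export
read_dist_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  dist_matrix(as.matrix(df))
}

#' @rdname dist-io
#' @export
write_dist_csv <- function(d, path) {
  d <- as.matrix(d)
  utils::write.csv(data.frame(d, check.names = FALSE), path)
  invisible(path)
}

#' @rdname dist-io
#' @export
read_dist_phylip <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1) stop("malformed PHYLIP matrix")
  toks <- lapply(lines[2:(n + 1)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(toks, `[`, "", 1)
  vals <- t(vapply(toks, function(tk) as.numeric(tk[-1]), numeric(n)))
  dist_matrix(vals, labels = labels)
}

#' @rdname dist-io
#' @export
write_dist_phylip <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(formatC(rownames(d)[i], width = -10),
                     paste(formatC(d[i, ], format = "f", digits = 6),
                           collapse = " ")), con)
  }
  invisible(path)
}
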