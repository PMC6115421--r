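#' @useDynLib brainblocks, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif var sd quantile coef lm optimize
#'   pnorm rbinom dist ecdf
#' @importFrom utils read.table write.table read.csv write.csv
NULL

# numerical tolerance for symmetry checks throughout the package
.SYM_TOL <- 1e-8

#' Weighted connectome object
#'
#' A `connectome` bundles one subject's symmetric, non-negative weighted
#' adjacency matrix (streamline-density-like units, zero diagonal) with node
#' metadata: hemisphere membership and 3-D coordinates in mm, as produced by
#' a cortical parcellation.
#'
#' @param weights n x n numeric matrix; must be symmetric to `1e-8`,
#'   non-negative, with zero diagonal.
#' @param nodes optional `data.frame` with columns `id`, `hemisphere`
#'   (`"L"`/`"R"`), `x`, `y`, `z` (mm) and `name`. Defaults to a minimal
#'   frame with ids only.
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, nodes = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("adjacency matrix must be square")
  asym <- max(abs(weights - t(weights)))
  if (asym > .SYM_TOL) {
    bad <- which(abs(weights - t(weights)) == asym, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "adjacency matrix not symmetric: entry (%d,%d) differs from (%d,%d) by %g",
      bad[1], bad[2], bad[2], bad[1], asym))
  }
  weights <- (weights + t(weights)) / 2
  if (any(weights < 0)) stop("adjacency matrix has negative weights")
  diag(weights) <- 0
  if (is.null(nodes)) {
    nodes <- data.frame(id = seq_len(n), hemisphere = NA_character_,
                        x = NA_real_, y = NA_real_, z = NA_real_,
                        name = paste0("node", seq_len(n)))
  }
  stopifnot(nrow(nodes) == n)
  dimnames(weights) <- NULL
  structure(list(weights = weights, nodes = nodes), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  dens <- edge_density(x)
  cat(sprintf("<connectome> %d nodes, binary density %.3f, total strength %.4g\n",
              n, dens, total_strength(x)))
  invisible(x)
}

#' Number of nodes of a connectome
#' @param A a `connectome` or square matrix
#' @return integer node count
#' @export
n_nodes <- function(A) nrow(conn_weights(A))

conn_weights <- function(A) {
  if (inherits(A, "connectome")) A$weights else as.matrix(A)
}

conn_coords <- function(A) {
  if (!inherits(A, "connectome") || anyNA(A$nodes$x)) {
    stop("node coordinates required but not available")
  }
  as.matrix(A$nodes[, c("x", "y", "z")])
}

#' Total network strength
#'
#' Sum of edge weights over the upper triangle: each undirected edge counted
#' once. This convention is shared by every module in the package.
#'
#' @inheritParams n_nodes
#' @return scalar total strength
#' @export
total_strength <- function(A) {
  W <- conn_weights(A)
  sum(W[upper.tri(W)])
}

#' Binary edge density
#' @inheritParams n_nodes
#' @return fraction of node pairs with nonzero weight
#' @export
edge_density <- function(A) {
  W <- conn_weights(A)
  n <- nrow(W)
  if (n < 2) return(0)
  sum(W[upper.tri(W)] > 0) / (n * (n - 1) / 2)
}

#' Node partition
#'
#' A block-label vector over nodes, labels in `1..k`. `k` may exceed
#' `max(labels)` to represent partitions with empty blocks (useful when
#' aligning label sets of different sizes).
#'
#' @param labels integer vector of block labels
#' @param k number of blocks; defaults to `max(labels)`
#' @return object of class `partition`
#' @export
partition <- function(labels, k = NULL) {
  labels <- as.integer(labels)
  if (length(labels) < 1) stop("empty label vector")
  if (any(is.na(labels)) || any(labels < 1)) stop("labels must be positive integers")
  if (is.null(k)) k <- max(labels)
  if (k < max(labels)) stop("k smaller than largest label")
  structure(list(labels = labels, k = as.integer(k)), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes, k = %d (%d non-empty)\n",
              length(x$labels), x$k, length(unique(x$labels))))
  invisible(x)
}

part_labels <- function(p) {
  if (inherits(p, "partition")) p$labels else as.integer(p)
}

part_k <- function(p) {
  if (inherits(p, "partition")) p$k else max(as.integer(p))
}

#' Block-pair index table
#'
#' Fixed ordering of the upper-triangle-plus-diagonal of a k x k block
#' matrix: pairs `(i, j)` with `i <= j`, ordered by `i` then `j`. The vector
#' length is `l = (k^2 - k) / 2 + k`.
#'
#' @param k block count
#' @return data.frame with columns `i`, `j` and `l` rows
#' @export
block_pairs <- function(k) {
  stopifnot(k >= 1)
  i <- unlist(lapply(seq_len(k), function(a) rep(a, k - a + 1)))
  j <- unlist(lapply(seq_len(k), function(a) a:k))
  data.frame(i = i, j = j)
}

#' Unroll a symmetric block matrix into a block vector
#'
#' @param M k x k symmetric matrix
#' @return numeric vector of length `(k^2 - k)/2 + k` in [block_pairs()] order
#' @export
unroll_blocks <- function(M) {
  M <- as.matrix(M)
  k <- nrow(M)
  bp <- block_pairs(k)
  M[cbind(bp$i, bp$j)]
}

#' Rebuild a symmetric block matrix from its unrolled vector
#' @param v block vector in [block_pairs()] order
#' @param k block count
#' @return k x k symmetric matrix
#' @export
roll_blocks <- function(v, k) {
  bp <- block_pairs(k)
  stopifnot(length(v) == nrow(bp))
  M <- matrix(0, k, k)
  M[cbind(bp$i, bp$j)] <- v
  M[cbind(bp$j, bp$i)] <- v
  M
}

# ---- file formats -----------------------------------------------------------
# Node ids are 1-based in every on-disk format and converted at this layer.

#' Read an adjacency matrix file
#'
#' Accepts dense whitespace- or comma-delimited square matrices, or
#' MatrixMarket coordinate files (detected by the `%%MatrixMarket` banner).
#'
#' @param path file path
#' @param nodes optional node metadata data.frame to attach
#' @return a `connectome`
#' @export
read_connectome <- function(path, nodes = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    M <- as.matrix(Matrix::readMM(path))
    # general-storage files may hold a single triangle; mirror it
    if (max(abs(M - t(M))) > .SYM_TOL) M <- pmax(M, t(M))
  } else {
    sep <- if (grepl(",", first)) "," else ""
    M <- as.matrix(read.table(path, sep = sep, header = FALSE))
  }
  connectome(M, nodes = nodes)
}

#' Write an adjacency matrix file
#'
#' @param A a `connectome` or matrix
#' @param path output path; a `.mtx` extension selects MatrixMarket output,
#'   anything else writes a dense whitespace-delimited matrix
#' @export
write_connectome <- function(A, path) {
  W <- conn_weights(A)
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(W, sparse = TRUE), path)
  } else {
    # %.17g keeps the dense round trip lossless for doubles
    write.table(matrix(formatC(W, format = "g", digits = 17), nrow(W)),
                path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read / write a partition as two-column TSV (node_id, block), 1-based
#' @param path file path
#' @return a `partition`
#' @export
read_partition <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  d <- d[order(d[[1]]), ]
  partition(d[[2]])
}

#' @rdname read_partition
#' @param p a `partition`
#' @export
write_partition <- function(p, path) {
  p <- partition(part_labels(p), part_k(p))
  write.table(data.frame(node_id = seq_along(p$labels), block = p$labels),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write node metadata TSV (id, hemisphere, x, y, z, name)
#' @param path file path
#' @return data.frame of node metadata
#' @export
read_nodes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_nodes
#' @param nodes node metadata data.frame
#' @export
write_nodes <- function(nodes, path) {
  write.table(nodes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minimum-weight filter and sparsity screen
#'
#' Emulates streamline-count noise filtering as a configurable weight floor:
#' entries strictly below `min_weight` are zeroed. Subjects whose filtered
#' binary density falls below `density_cutoff` are flagged for exclusion.
#'
#' @param A `connectome`
#' @param min_weight weights below this are set to 0 (default 0 = identity)
#' @param density_cutoff minimum acceptable binary edge density (default 0.25)
#' @return the filtered `connectome`, with attribute `excluded` set to TRUE
#'   when the density cutoff is not reached
#' @export
apply_input_filters <- function(A, min_weight = 0, density_cutoff = 0.25) {
  W <- conn_weights(A)
  W[W < min_weight] <- 0
  out <- connectome(W, nodes = if (inherits(A, "connectome")) A$nodes else NULL)
  attr(out, "excluded") <- edge_density(out) < density_cutoff
  out
}
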