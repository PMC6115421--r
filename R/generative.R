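# Generative model evaluation: synthesize network ensembles from fitted
# block parameters and score each replicate's binary network statistics
# against the empirical network with the Kolmogorov-Smirnov statistic.
# KS energy is the MEAN of the four KS components (not the max), so no
# single statistic dominates the score.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the two empirical cumulative
#' distribution functions, evaluated over the pooled sample points.
#'
#' @param x,y non-empty numeric samples
#' @return scalar in `[0, 1]`
#' @export
ks_statistic <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}

#' Binary node statistics for generative evaluation
#'
#' Computes, on the binarized network: degree, local clustering coefficient
#' (0 for nodes of degree < 2), unnormalized shortest-path betweenness
#' centrality (pair counts, unit edge lengths), and node Euclidean distance
#' (mean distance in mm from the node to its connected neighbours;
#' `distance_mode = "total"` sums instead). Isolated nodes score 0 on all
#' four.
#'
#' @param A `connectome`, or binary/weighted matrix (binarized internally)
#' @param coords optional n x 3 coordinate matrix (taken from `A`'s node
#'   metadata when absent)
#' @param distance_mode `"mean"` (default) or `"total"`
#' @return list with numeric vectors `degree`, `clustering`, `betweenness`,
#'   `distance`
#' @export
node_statistics <- function(A, coords = NULL, distance_mode = c("mean", "total")) {
  distance_mode <- match.arg(distance_mode)
  if (is.null(coords)) coords <- conn_coords(A)
  X <- (conn_weights(A) > 0) * 1
  n <- nrow(X)
  g <- igraph::graph_from_adjacency_matrix(X, mode = "undirected")
  deg <- as.numeric(igraph::degree(g))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  btw <- as.numeric(igraph::betweenness(g, directed = FALSE, weights = NA))
  D <- as.matrix(dist(coords))
  ed <- vapply(seq_len(n), function(i) {
    nb <- which(X[i, ] > 0)
    if (length(nb) == 0) return(0)
    if (distance_mode == "mean") mean(D[i, nb]) else sum(D[i, nb])
  }, numeric(1))
  list(degree = deg, clustering = cc, betweenness = btw, distance = ed)
}

#' Evaluate a generative block model by KS energy
#'
#' Per replicate: sample a synthetic network from `params` under the fixed
#' `partition`, binarize, compute the four binary node statistics, and take
#' the KS statistic of each against the empirical network's statistic
#' distribution. The replicate energy is the mean of the four KS components.
#'
#' @param params `wsbm_params`
#' @param p `partition` used for sampling
#' @param empirical empirical `connectome` (must carry node coordinates)
#' @param n_replicates number of synthetic networks (default 10000;
#'   scale down for desk runs)
#' @param seed RNG seed
#' @param distance_mode passed to [node_statistics()]
#' @return object of class `eval_result`: data.frame `replicates` with
#'   columns `ks_degree`, `ks_clustering`, `ks_betweenness`, `ks_distance`,
#'   `energy`, plus `mean_energy`
#' @export
evaluate_model <- function(params, p, empirical, n_replicates = 10000L,
                           seed = 1L, distance_mode = "mean") {
  coords <- conn_coords(empirical)
  emp <- node_statistics(empirical, coords, distance_mode)
  seeds <- .trial_seeds(seed, n_replicates)
  rows <- vapply(seeds, function(s) {
    syn <- sample_network(params, p, seed = s)
    st <- node_statistics(syn, coords, distance_mode)
    c(ks_statistic(st$degree, emp$degree),
      ks_statistic(st$clustering, emp$clustering),
      ks_statistic(st$betweenness, emp$betweenness),
      ks_statistic(st$distance, emp$distance))
  }, numeric(4))
  reps <- data.frame(ks_degree = rows[1, ], ks_clustering = rows[2, ],
                     ks_betweenness = rows[3, ], ks_distance = rows[4, ])
  reps$energy <- rowMeans(reps)
  structure(list(replicates = reps, mean_energy = mean(reps$energy),
                 n_replicates = n_replicates), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %d replicates, mean KS energy %.4f\n",
              x$n_replicates, x$mean_energy))
  invisible(x)
}

#' Randomly permute block-model parameters
#'
#' Applies one random permutation jointly to the upper-triangle-plus-diagonal
#' entries of the (edge_rate, weight_mean, weight_var) triplets, preserving
#' symmetry; the multiset of parameter triplets is unchanged. Serves as the
#' permuted-parameter null for generative evaluation.
#'
#' @param params `wsbm_params`
#' @param seed RNG seed
#' @return a permuted `wsbm_params`
#' @export
permuted_model <- function(params, seed = 1L) {
  k <- params$k
  v_rate <- unroll_blocks(params$edge_rate)
  v_mean <- unroll_blocks(params$weight_mean)
  v_var <- unroll_blocks(params$weight_var)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  perm <- sample(length(v_rate))
  wsbm_params(roll_blocks(v_rate[perm], k),
              roll_blocks(v_mean[perm], k),
              roll_blocks(v_var[perm], k))
}

#' Block parameters of a fixed (modular) partition
#'
#' Parameter estimation without membership inference: under the given
#' partition, each block pair's edge-existence rate is the observed binary
#' density inverted to the truncated-Poisson scale
#' (`rate = -log(1 - density)`), and weight mean/variance come from the
#' observed nonzero weights of that pair. Deterministic given `A` and `p`.
#'
#' @param A `connectome` or matrix
#' @param p fixed `partition`
#' @param var_floor variance floor for pairs with < 2 edges
#' @return list with `params` (`wsbm_params`) and `partition`
#' @export
modular_as_generative <- function(A, p, var_floor = 1e-6) {
  W <- conn_weights(A)
  labels <- part_labels(p)
  k <- part_k(p)
  iu <- which(upper.tri(W))
  bi <- pmin(labels[row(W)[iu]], labels[col(W)[iu]])
  bj <- pmax(labels[row(W)[iu]], labels[col(W)[iu]])
  pairkey <- (bi - 1) * k + bj
  rate <- mu <- s2 <- matrix(0, k, k)
  glob_mu <- if (any(W[iu] > 0)) mean(W[iu][W[iu] > 0]) else 0
  bp <- block_pairs(k)
  for (r in seq_len(nrow(bp))) {
    sel <- pairkey == (bp$i[r] - 1) * k + bp$j[r]
    npairs <- sum(sel)
    w <- W[iu][sel]
    dens <- if (npairs > 0) mean(w > 0) else 0
    th <- -log(1 - min(dens, 1 - 1e-9))
    wm <- if (any(w > 0)) mean(w[w > 0]) else glob_mu
    wv <- if (sum(w > 0) >= 2) max(var(w[w > 0]), var_floor) else var_floor
    i <- bp$i[r]; j <- bp$j[r]
    rate[i, j] <- rate[j, i] <- th
    mu[i, j] <- mu[j, i] <- wm
    s2[i, j] <- s2[j, i] <- wv
  }
  list(params = wsbm_params(rate, mu, s2), partition = partition(labels, k))
}
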