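# Community-conditional node statistics, laterality, high-degree-node
# consistency (ICC), spatial compactness, and across-subject versatility
# with permutation inference.

#' Weighted participation coefficient
#'
#' `P_i = 1 - sum_s (w_is / w_i)^2` over communities `s`, with `w_is` the
#' node's total weight into community `s` and `w_i` its strength. Nodes with
#' zero strength score 0.
#'
#' @param A `connectome` or matrix
#' @param p `partition`
#' @return per-node vector in `[0, 1]`
#' @export
participation_coefficient <- function(A, p) {
  W <- conn_weights(A)
  lab <- part_labels(p)
  k <- part_k(p)
  Ws <- vapply(seq_len(k), function(s) rowSums(W[, lab == s, drop = FALSE]),
               numeric(nrow(W)))
  tot <- rowSums(W)
  out <- 1 - rowSums((Ws / pmax(tot, .Machine$double.xmin))^2)
  out[tot == 0] <- 0
  out
}

#' Within-module degree z-score (weighted)
#'
#' Each node's within-community strength standardized within its own
#' community. Singleton communities and communities with zero strength
#' spread return 0.
#'
#' @inheritParams participation_coefficient
#' @return per-node vector
#' @export
within_module_z <- function(A, p) {
  W <- conn_weights(A)
  lab <- part_labels(p)
  kappa <- vapply(seq_len(nrow(W)), function(i) {
    sum(W[i, lab == lab[i]])
  }, numeric(1))
  out <- numeric(length(lab))
  for (s in unique(lab)) {
    idx <- which(lab == s)
    if (length(idx) < 2) next
    mu <- mean(kappa[idx]); sdv <- sd(kappa[idx])
    if (sdv > 0) out[idx] <- (kappa[idx] - mu) / sdv
  }
  out
}

#' Per-node decomposition of weighted degree assortativity
#'
#' The global weighted assortativity is the weighted Pearson correlation,
#' over edge endpoints, of endpoint strengths:
#' r = sum_ij W_ij (s_i - mu)(s_j - mu) / (S * sigma^2), with S = sum(W)
#' and mu, sigma^2 the W-weighted mean and variance of strengths at edge
#' ends. The per-node contribution
#' c_i = sum_j W_ij (s_i - mu)(s_j - mu) / (S * sigma^2) sums exactly to
#' the global coefficient; community assortativity is the sum of its
#' members' contributions.
#'
#' @inheritParams participation_coefficient
#' @return per-node contribution vector (attribute `global` holds `r`)
#' @export
node_assortativity <- function(A, p = NULL) {
  W <- conn_weights(A)
  s <- colSums(W)
  S <- sum(W)
  if (S == 0) return(structure(numeric(nrow(W)), global = 0))
  mu <- sum(rowSums(W) * s) / S
  sig2 <- sum(rowSums(W) * (s - mu)^2) / S
  if (sig2 == 0) return(structure(numeric(nrow(W)), global = 0))
  contrib <- as.numeric((s - mu) * (W %*% (s - mu))) / (S * sig2)
  structure(contrib, global = sum(contrib))
}

#' Community assortativity totals
#' @inheritParams participation_coefficient
#' @return per-community sums of node assortativity contributions
#' @export
community_assortativity <- function(A, p) {
  contrib <- node_assortativity(A)
  lab <- part_labels(p)
  vapply(seq_len(part_k(p)), function(s) sum(contrib[lab == s]), numeric(1))
}

#' Hemispheric laterality of a node statistic
#'
#' KS statistic between the left- and right-hemisphere distributions of a
#' per-node statistic: 0 when the hemispheres are distributionally
#' identical, 1 when their supports are disjoint.
#'
#' @param values per-node numeric vector
#' @param hemispheres per-node `"L"`/`"R"` labels
#' @return scalar in `[0, 1]`
#' @export
laterality_ks <- function(values, hemispheres) {
  stopifnot(length(values) == length(hemispheres))
  ks_statistic(values[hemispheres == "L"], values[hemispheres == "R"])
}

#' Spatial compactness of a partition
#'
#' Sum over communities of all within-community pairwise Euclidean
#' distances (mm).
#'
#' @param p `partition`
#' @param coords n x 3 coordinate matrix (mm)
#' @return total mm
#' @export
compactness <- function(p, coords) {
  lab <- part_labels(p)
  D <- as.matrix(dist(coords))
  tot <- 0
  for (s in unique(lab)) {
    idx <- which(lab == s)
    if (length(idx) > 1) tot <- tot + sum(D[idx, idx][upper.tri(D[idx, idx])])
  }
  tot
}

#' ICC(3,1): two-way mixed, single measures, consistency
#'
#' @param M targets x raters numeric matrix
#' @return scalar ICC(3,1) = (BMS - EMS) / (BMS + (r-1) EMS)
#' @export
icc31 <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M); r <- ncol(M)
  stopifnot(n >= 2, r >= 2)
  grand <- mean(M)
  BMS <- r * sum((rowMeans(M) - grand)^2) / (n - 1)
  JMS <- n * sum((colMeans(M) - grand)^2) / (r - 1)
  SST <- sum((M - grand)^2)
  EMS <- (SST - BMS * (n - 1) - JMS * (r - 1)) / ((n - 1) * (r - 1))
  (BMS - EMS) / (BMS + (r - 1) * EMS)
}

#' Consistency of high-degree node dispersion across communities
#'
#' For each subject, counts how many of that subject's top-fraction
#' highest-degree nodes (ceiling rounding; threshold ties broken by node
#' index) fall into each community of the subject's (aligned) partition.
#' ICC(3,1) is computed on the resulting communities x subjects count
#' matrix, with communities as targets and subjects as raters. A bootstrap
#' confidence interval resamples subjects.
#'
#' @param partitions_by_subject list of aligned `partition`s (one per
#'   subject, common k)
#' @param A_by_subject list of `connectome`s or matrices, same order
#' @param top_frac fraction of nodes counted as high-degree (default 0.25)
#' @param degree_kind `"binary"` or `"weighted"` node degree
#' @param n_boot bootstrap draws for the CI (default 500)
#' @param conf CI level (default 0.95)
#' @param seed RNG seed for the bootstrap
#' @return list: `icc`, `ci` (two-sided percentile bootstrap), `counts`
#'   (k x n_subjects matrix)
#' @export
top_degree_dispersion_icc <- function(partitions_by_subject, A_by_subject,
                                      top_frac = 0.25,
                                      degree_kind = c("binary", "weighted"),
                                      n_boot = 500L, conf = 0.95, seed = 1L) {
  degree_kind <- match.arg(degree_kind)
  stopifnot(length(partitions_by_subject) == length(A_by_subject))
  k <- part_k(partitions_by_subject[[1]])
  counts <- vapply(seq_along(A_by_subject), function(si) {
    W <- conn_weights(A_by_subject[[si]])
    deg <- if (degree_kind == "binary") rowSums(W > 0) else rowSums(W)
    ntop <- ceiling(top_frac * length(deg))
    top <- order(-deg, seq_along(deg))[seq_len(ntop)]  # ties by node index
    tabulate(part_labels(partitions_by_subject[[si]])[top], nbins = k)
  }, numeric(k))
  icc <- icc31(counts)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    icc31(counts[, sample(ncol(counts), replace = TRUE), drop = FALSE])
  }, numeric(1))
  a <- (1 - conf) / 2
  list(icc = icc, ci = unname(quantile(boots, c(a, 1 - a), na.rm = TRUE)),
       counts = counts)
}

#' Across-subject node versatility
#'
#' After Munkres-aligning every subject's partition column to a reference,
#' node versatility is the Shannon entropy (nats) of the node's
#' across-subject block-frequency vector: 0 iff the node always lands in
#' one block, at most `log(k)`.
#'
#' @param assignments n_nodes x n_subjects integer label matrix
#' @param reference optional reference `partition` for alignment (default:
#'   the first subject's column); set `align = FALSE` if columns are
#'   pre-aligned
#' @param align perform Munkres alignment first (default TRUE)
#' @return per-node entropy vector (nats)
#' @export
versatility <- function(assignments, reference = NULL, align = TRUE) {
  M <- as.matrix(assignments)
  k <- max(M)
  if (align) {
    if (is.null(reference)) reference <- partition(M[, 1], k = k)
    k <- max(k, part_k(reference))
    cols <- align_partitions(lapply(seq_len(ncol(M)), function(j) {
      partition(M[, j], k = k)
    }), reference)
    M <- vapply(cols, part_labels, integer(nrow(M)))
    k <- max(vapply(cols, part_k, integer(1)))
  }
  apply(M, 1, function(r) {
    f <- tabulate(r, nbins = k) / length(r)
    f <- f[f > 0]
    -sum(f * log(f))
  })
}

#' Permutation test for versatility differences between two methods
#'
#' For each permutation, each subject's column is randomly swapped between
#' the two node x subject assignment matrices (method exchangeability
#' null); the per-node versatility difference is recomputed to build a null
#' distribution. Two-sided p-values per node, with a Bonferroni mask at the
#' node-count family size.
#'
#' @param assignA,assignB n_nodes x n_subjects label matrices
#'   (method A and B)
#' @param n_perm number of permutations (default 10000)
#' @param seed RNG seed
#' @param reference optional alignment reference passed to [versatility()]
#' @return data.frame: node, difference (A - B), p, significant
#'   (Bonferroni at `0.05 / n_nodes`)
#' @export
versatility_difference_test <- function(assignA, assignB, n_perm = 10000L,
                                        seed = 1L, reference = NULL) {
  A <- as.matrix(assignA); B <- as.matrix(assignB)
  stopifnot(all(dim(A) == dim(B)))
  n <- nrow(A); ns <- ncol(A)
  vA <- versatility(A, reference = reference)
  vB <- versatility(B, reference = reference)
  obs <- vA - vB
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  exceed <- numeric(n)
  for (b in seq_len(n_perm)) {
    swap <- runif(ns) < 0.5
    PA <- A; PB <- B
    PA[, swap] <- B[, swap]
    PB[, swap] <- A[, swap]
    d <- versatility(PA, reference = reference) -
         versatility(PB, reference = reference)
    exceed <- exceed + (abs(d) >= abs(obs))
  }
  p <- (1 + exceed) / (1 + n_perm)
  alpha <- 0.05 / n
  data.frame(node = seq_len(n), difference = obs, p = p,
             significant = p < alpha)
}
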