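# Staged WSBM fitting workflow: broad uniform-prior search, concentration
# refinement, k selection by mean log-evidence (Bayes factors), frequency-
# prior consensus iteration, and consensus-seeded subject-level fits.

.trial_seeds <- function(seed, n) {
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Stage-1 broad search: best of many uniform-prior fits
#'
#' Runs `n_trials` independent variational fits seeded from a uniform block
#' assignment prior and keeps the one with the highest lower bound.
#'
#' @param A `connectome` or matrix
#' @param k block count
#' @param n_trials number of independent trials (default 250)
#' @param seed seed for the trial seed stream
#' @param ... passed to [fit_wsbm()] (`alpha`, `tol`, `max_iter`)
#' @return the best `wsbm_fit`
#' @export
stage1_fit <- function(A, k, n_trials = 250L, seed = 1L, ...) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  seeds <- .trial_seeds(seed, n_trials)
  best <- NULL
  for (s in seeds) {
    f <- fit_wsbm(A, k, prior = NULL, seed = s, ...)
    if (is.null(best) || f$log_evidence > best$log_evidence) best <- f
  }
  best
}

#' Stage-2 refinement with a concentration ladder
#'
#' Iteratively refits with increasingly concentrated assignment priors: at
#' ladder increment `c`, each node's current MAP block receives prior weight
#' `1 + c` against 1 for the other blocks (so `c = 1` is a "100% higher"
#' prior). The default ladder `1.0, 1.5, 2.0, ..., 6.0` reproduces the
#' 100% then 150%...600% concentration ramp. The best posterior seen at any
#' level is returned.
#'
#' @param A `connectome` or matrix
#' @param k block count
#' @param seed_partition `partition` seeding the first biased prior
#' @param ladder numeric vector of concentration increments `c >= 0`
#' @param n_trials fits per ladder level (default 100)
#' @param seed seed for the trial seed streams
#' @param ... passed to [fit_wsbm()]
#' @return the best `wsbm_fit` across all levels
#' @export
stage2_refine <- function(A, k, seed_partition,
                          ladder = seq(1, 6, by = 0.5),
                          n_trials = 100L, seed = 1L, ...) {
  if (length(ladder) < 1) stop("empty concentration ladder")
  current <- seed_partition
  best <- NULL
  seeds <- .trial_seeds(seed, length(ladder))
  for (lv in seq_along(ladder)) {
    pr <- concentrated_prior(current, k = k, concentration = 1 + ladder[lv])
    lv_best <- NULL
    for (s in .trial_seeds(seeds[lv], n_trials)) {
      f <- fit_wsbm(A, k, prior = pr, seed = s, ...)
      if (is.null(lv_best) || f$log_evidence > lv_best$log_evidence) lv_best <- f
    }
    current <- lv_best$map_partition
    if (is.null(best) || lv_best$log_evidence > best$log_evidence) best <- lv_best
  }
  best
}

#' Select the number of blocks by mean log-evidence
#'
#' Fits the WSBM `n_fits` times at each candidate `k` and records the mean
#' variational log-evidence; differences between these means act as
#' Bayes-factor comparisons. Returns the `k` with the highest mean (ties to
#' the lowest `k`) together with the full evidence table.
#'
#' @param A `connectome` or matrix
#' @param k_range integer vector of candidate block counts (default 6:11)
#' @param n_fits fits per candidate (default 100)
#' @param seed seed for the trial seed streams
#' @param ... passed to [fit_wsbm()]
#' @return list with `k` (selected) and `table`
#'   (data.frame: k, mean_log_evidence, sd_log_evidence)
#' @export
select_k <- function(A, k_range = 6:11, n_fits = 100L, seed = 1L, ...) {
  if (length(k_range) < 1) stop("empty k range")
  seeds <- .trial_seeds(seed, length(k_range))
  rows <- lapply(seq_along(k_range), function(i) {
    ev <- vapply(.trial_seeds(seeds[i], n_fits), function(s) {
      fit_wsbm(A, k_range[i], seed = s, ...)$log_evidence
    }, numeric(1))
    data.frame(k = k_range[i], mean_log_evidence = mean(ev),
               sd_log_evidence = if (n_fits > 1) sd(ev) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  list(k = tab$k[which.max(tab$mean_log_evidence)], table = tab)
}

#' Frequency-prior consensus loop
#'
#' One outer iteration: run `n_fits` fits seeded by the current assignment
#' prior, take the VI-centroid of the MAP partitions, align the rest to it
#' with the Munkres algorithm, average the aligned assignments into an
#' n x k frequency matrix (rows sum to 1), and use it as the next prior.
#' The loop stops when the consensus partition is identical (VI = 0 after
#' alignment) between successive iterations, or after `max_outer` rounds.
#'
#' @param A `connectome` or matrix
#' @param k block count
#' @param n_fits fits per outer iteration (default 100)
#' @param seed seed for the trial seed streams
#' @param max_outer outer-iteration cap (default 10)
#' @param init_prior optional starting n x k concentration matrix
#' @param ... passed to [fit_wsbm()]
#' @return list of class `consensus_result`: `partition`, `frequency_prior`
#'   (n x k, rows sum to 1), `n_outer_iterations`, `converged`, `fit_log`
#'   (per-iteration VI and NMI to the previous consensus), and
#'   `aligned_labels` (n x n_fits aligned label matrix of the final
#'   iteration, usable for bootstrap stability checks)
#' @export
consensus_loop <- function(A, k, n_fits = 100L, seed = 1L, max_outer = 10L,
                           init_prior = NULL, ...) {
  n <- n_nodes(if (inherits(A, "connectome")) A else connectome(A))
  prior <- init_prior
  prev <- NULL
  freq <- NULL
  converged <- FALSE
  fit_log <- data.frame(iteration = integer(), vi = numeric(), nmi = numeric())
  outer_seeds <- .trial_seeds(seed, max_outer)
  it <- 0L
  for (it in seq_len(max_outer)) {
    fits <- lapply(.trial_seeds(outer_seeds[it], n_fits), function(s) {
      fit_wsbm(A, k, prior = prior, seed = s, ...)
    })
    parts <- lapply(fits, `[[`, "map_partition")
    ctr <- find_centroid(parts)
    aligned <- align_partitions(parts, parts[[ctr]])
    M <- vapply(aligned, part_labels, integer(n))
    freq <- t(apply(M, 1, function(r) tabulate(r, nbins = k))) / ncol(M)
    consensus <- partition(max.col(freq, ties.method = "first"), k = k)
    if (!is.null(prev)) {
      fit_log <- rbind(fit_log, data.frame(
        iteration = it, vi = vi_distance(consensus, prev),
        nmi = nmi(consensus, prev)))
      if (vi_distance(consensus, prev) == 0) {
        prev <- consensus
        converged <- TRUE
        break
      }
    }
    prev <- consensus
    prior <- frequency_prior(freq)
  }
  structure(list(partition = prev, frequency_prior = freq,
                 n_outer_iterations = it, converged = converged,
                 fit_log = fit_log, aligned_labels = M),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k = %d, %s after %d outer iterations\n",
              x$partition$k,
              if (x$converged) "converged" else "NOT converged",
              x$n_outer_iterations))
  invisible(x)
}

#' Consensus-seeded subject-level fit
#'
#' Fits the WSBM to one subject's network with a prior concentrated on the
#' consensus partition (default level 3: the consensus block is 3x more
#' likely a priori than any other). Collects `n_fits` independent fits and
#' returns the VI-centroid of their MAP partitions.
#'
#' @param A subject `connectome` or matrix
#' @param consensus consensus `partition`
#' @param concentration prior weight of the consensus block (default 3)
#' @param n_fits number of independent fits (default 5)
#' @param seed seed for the trial seed stream
#' @param ... passed to [fit_wsbm()]
#' @return the centroid `partition`
#' @export
fit_subject <- function(A, consensus, concentration = 3, n_fits = 5L,
                        seed = 1L, ...) {
  n <- n_nodes(if (inherits(A, "connectome")) A else connectome(A))
  if (length(part_labels(consensus)) != n) {
    stop("consensus partition does not match the network's node count")
  }
  k <- part_k(consensus)
  pr <- concentrated_prior(consensus, k = k, concentration = concentration)
  fits <- lapply(.trial_seeds(seed, n_fits), function(s) {
    fit_wsbm(A, k, prior = pr, seed = s, ...)
  })
  parts <- lapply(fits, `[[`, "map_partition")
  parts[[find_centroid(parts)]]
}
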