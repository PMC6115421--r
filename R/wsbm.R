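# Weighted stochastic block model: generative sampling and variational-Bayes
# inference with configurable block-assignment priors.
#
# Generative model, per unordered node pair with blocks (r, s):
#   presence  x ~ Poisson(theta_rs), truncated so a count >= 1 is an edge;
#   weight    w ~ Normal(mu_rs, sigma2_rs) for present edges only.
# The two likelihood components are combined with a mixing weight alpha
# (default 0.5). Conjugate variational posteriors: Gamma on theta,
# Normal-Gamma on (mu, precision), per-node categorical assignments.

#' WSBM block parameters
#'
#' @param edge_rate k x k symmetric matrix of Poisson edge-existence rates
#' @param weight_mean k x k symmetric matrix of edge-weight means
#' @param weight_var k x k symmetric matrix of edge-weight variances (> 0)
#' @return object of class `wsbm_params`
#' @export
wsbm_params <- function(edge_rate, weight_mean, weight_var) {
  chk <- function(M, nm) {
    M <- as.matrix(M)
    if (nrow(M) != ncol(M)) stop(nm, " must be square")
    if (max(abs(M - t(M))) > .SYM_TOL) stop(nm, " must be symmetric")
    M
  }
  edge_rate <- chk(edge_rate, "edge_rate")
  weight_mean <- chk(weight_mean, "weight_mean")
  weight_var <- chk(weight_var, "weight_var")
  if (any(edge_rate < 0)) stop("edge_rate must be non-negative")
  if (any(weight_var <= 0)) stop("weight_var must be positive")
  stopifnot(all(dim(edge_rate) == dim(weight_mean)),
            all(dim(edge_rate) == dim(weight_var)))
  structure(list(edge_rate = edge_rate, weight_mean = weight_mean,
                 weight_var = weight_var, k = nrow(edge_rate)),
            class = "wsbm_params")
}

#' Uniform / concentrated / frequency block-assignment priors
#'
#' Assignment priors are n x k non-negative concentration matrices; each row
#' is normalised to a categorical prior over blocks. `uniform_prior` weights
#' all blocks equally. `concentrated_prior` gives each node's designated
#' block a weight of `concentration` against 1 for the others (so
#' `concentration = 2` means "100% higher likelihood"). `frequency_prior`
#' turns an n x k frequency matrix into a prior, flooring entries at
#' `floor_frac / k` so no block is locked out entirely.
#'
#' @param n node count
#' @param k block count
#' @return n x k concentration matrix
#' @export
uniform_prior <- function(n, k) matrix(1, n, k)

#' @rdname uniform_prior
#' @param p a `partition` whose labels receive the concentrated weight
#' @param concentration prior weight of the designated block (>= 1)
#' @export
concentrated_prior <- function(p, k = part_k(p), concentration = 3) {
  labels <- part_labels(p)
  M <- matrix(1, length(labels), k)
  M[cbind(seq_along(labels), labels)] <- concentration
  M
}

#' @rdname uniform_prior
#' @param freq n x k matrix of assignment frequencies (rows sum to 1)
#' @param floor_frac positive floor applied as `floor_frac / k`
#' @export
frequency_prior <- function(freq, floor_frac = 0.01) {
  M <- pmax(as.matrix(freq), floor_frac / ncol(freq))
  M / rowSums(M)
}

.spectral_init <- function(W, k, dims = k) {
  n <- nrow(W)
  if (k == 1) return(rep(1L, n))
  z <- tryCatch({
    e <- eigen(W, symmetric = TRUE)
    idx <- order(-abs(e$values))[seq_len(min(dims, n))]
    emb <- e$vectors[, idx, drop = FALSE] %*%
      diag(sqrt(abs(e$values[idx])), length(idx))
    stats::kmeans(emb, centers = k, nstart = 5, iter.max = 25)$cluster
  }, error = function(err) NULL)
  if (is.null(z)) z <- sample.int(k, n, replace = TRUE)
  as.integer(z)
}

.kl_gamma <- function(a, b, a0, b0) {
  (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
}

#' Fit the weighted stochastic block model by variational Bayes
#'
#' Coordinate-ascent variational inference with conjugate priors: Gamma(1, 1)
#' on edge-existence rates, Normal-Gamma (centred on the sample mean/variance
#' of nonzero weights, kappa0 = a0 = 1) on weight mean/precision, and a
#' per-node categorical assignment prior given by `prior`. Missing edges
#' contribute only to the presence component; weights are modelled
#' conditionally on existence. The evidence lower bound is non-decreasing
#' across iterations (asserted on every run) and iteration stops when its
#' absolute change falls below `tol` or after `max_iter` sweeps.
#'
#' @param A `connectome` or symmetric non-negative matrix
#' @param k number of blocks (`1 <= k <= n`)
#' @param prior n x k concentration matrix (default uniform)
#' @param seed RNG seed for the responsibility initialisation
#' @param alpha mixing weight between the presence and weight likelihood
#'   components, in (0, 1); default 0.5
#' @details Initialisation: uniform-prior trials start from a randomized
#'   spectral embedding (top-k adjacency eigenvectors, one random-start
#'   k-means), which varies across seeds while avoiding the one-block local
#'   optimum; biased-prior trials start from a random draw of the prior.
#' @param tol absolute lower-bound change convergence threshold (nats)
#' @param max_iter maximum number of coordinate-ascent sweeps
#' @param init_labels optional integer label vector fixing the initial hard
#'   assignments (defaults to a random draw from the prior)
#' @return object of class `wsbm_fit`: `responsibilities` (n x k,
#'   row-stochastic), `params` (`wsbm_params`; `edge_rate` is reported on
#'   the generative truncated-Poisson scale, i.e. `-log(1 - p)` of the
#'   posterior-mean presence probability, so that [sample_network()]
#'   reproduces fitted edge densities),
#'   `log_evidence` (variational lower bound, nats), `map_partition`
#'   (row-wise argmax, ties to the lowest block), `elbo_trace`, `converged`,
#'   `k`, `alpha`
#' @export
fit_wsbm <- function(A, k, prior = NULL, seed = 1L, alpha = 0.5,
                     tol = 1e-4, max_iter = 200L, init_labels = NULL) {
  A <- if (inherits(A, "connectome")) A else connectome(A)
  W <- conn_weights(A)
  n <- nrow(W)
  stopifnot(k >= 1, n >= k)
  X <- (W > 0) * 1
  if (sum(X) == 0 && k > 1) {
    warning("degenerate fit: empty network with k > 1")
  }
  if (is.null(prior)) prior <- uniform_prior(n, k)
  prior <- as.matrix(prior)
  stopifnot(all(dim(prior) == c(n, k)), all(prior >= 0),
            all(rowSums(prior) > 0))
  pi_prior <- prior / rowSums(prior)
  logprior <- log(pmax(pi_prior, 1e-300))

  # data-scaled weak hyperpriors
  wnz <- W[upper.tri(W)][X[upper.tri(X)] > 0]
  m0 <- if (length(wnz) > 0) mean(wnz) else 0
  v0 <- if (length(wnz) > 1 && var(wnz) > 0) var(wnz) else 1
  a0_th <- 1; b0_th <- 1
  kappa0 <- 1; a0_ng <- 1; b0_ng <- v0

  XW <- X * W
  XW2 <- X * W * W

  # random hard one-hot initial assignments drawn from the prior: a soft
  # symmetric start lets the first M-step average all blocks together and
  # the ascent collapses to one block, so symmetry is broken at init
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  uniform <- max(pi_prior) - min(pi_prior) < 1e-12
  z0 <- if (!is.null(init_labels)) {
    stopifnot(length(init_labels) == n, all(init_labels %in% 1:k))
    as.integer(init_labels)
  } else if (uniform) {
    # uniform-prior trials: randomized spectral start (adjacency spectral
    # embedding + one random-start k-means); plain random labels leave
    # coordinate ascent in the one-block basin far too often
    .spectral_init(W, k)
  } else {
    # biased-prior trials start from a draw of the prior itself
    vapply(seq_len(n), function(i) {
      sample.int(k, 1, prob = pi_prior[i, ])
    }, integer(1))
  }
  tau <- matrix(0, n, k)
  tau[cbind(seq_len(n), z0)] <- 1

  mstep <- function(tau) {
    cs <- colSums(tau)
    Tfull <- crossprod(tau, X %*% tau)
    Nfull <- outer(cs, cs) - crossprod(tau)
    W1full <- crossprod(tau, XW %*% tau)
    W2full <- crossprod(tau, XW2 %*% tau)
    # symmetrise against numerical drift
    Tfull <- (Tfull + t(Tfull)) / 2; Nfull <- (Nfull + t(Nfull)) / 2
    W1full <- (W1full + t(W1full)) / 2; W2full <- (W2full + t(W2full)) / 2
    half <- function(M) { diag(M) <- diag(M) / 2; M }
    Th <- half(Tfull); Nh <- half(Nfull)
    W1h <- half(W1full); W2h <- half(W2full)

    a_th <- a0_th + alpha * Th
    b_th <- b0_th + alpha * Nh
    nt <- (1 - alpha) * Th
    St <- (1 - alpha) * W1h
    Qt <- (1 - alpha) * W2h
    kap <- kappa0 + nt
    m_q <- (kappa0 * m0 + St) / kap
    a_ng <- a0_ng + nt / 2
    b_ng <- pmax(b0_ng + 0.5 * (Qt + kappa0 * m0^2 - kap * m_q^2), 1e-12)

    list(a_th = a_th, b_th = b_th, kap = kap, m_q = m_q,
         a_ng = a_ng, b_ng = b_ng,
         elog_theta = digamma(a_th) - log(b_th), e_theta = a_th / b_th,
         elog_lam = digamma(a_ng) - log(b_ng), ab = a_ng / b_ng,
         inv_kappa = 1 / kap,
         Tfull = Tfull, Nfull = Nfull, W1full = W1full, W2full = W2full)
  }

  elbo <- function(tau, P) {
    lik <- 0.5 * sum(
      alpha * (P$Tfull * P$elog_theta - P$Nfull * P$e_theta) +
      (1 - alpha) * (P$Tfull * (0.5 * (P$elog_lam - log(2 * pi)) -
                                 0.5 * P$inv_kappa) -
                     0.5 * P$ab * (P$W2full - 2 * P$m_q * P$W1full +
                                   P$m_q^2 * P$Tfull)))
    tlt <- tau * (logprior - log(pmax(tau, 1e-300)))
    ent <- sum(tlt[tau > 0])
    ut <- upper.tri(P$a_th, diag = TRUE)
    kl_th <- sum(.kl_gamma(P$a_th, P$b_th, a0_th, b0_th)[ut])
    kl_ng <- sum((0.5 * log(P$kap / kappa0) - 0.5 +
                  (kappa0 / 2) * (P$ab * (P$m_q - m0)^2 + 1 / P$kap) +
                  .kl_gamma(P$a_ng, P$b_ng, a0_ng, b0_ng))[ut])
    lik + ent - kl_th - kl_ng
  }

  P <- mstep(tau)
  bound <- elbo(tau, P)
  trace <- bound
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    tau <- vb_estep_sweep(tau, X, W, logprior, P$elog_theta, P$e_theta,
                          P$elog_lam, P$ab, P$m_q, P$inv_kappa, alpha)
    P <- mstep(tau)
    new_bound <- elbo(tau, P)
    if (new_bound < bound - 1e-6) {
      stop(sprintf("lower bound decreased (%.3e) at iteration %d",
                   bound - new_bound, it))
    }
    trace <- c(trace, new_bound)
    if (abs(new_bound - bound) < tol) { bound <- new_bound; converged <- TRUE; break }
    bound <- new_bound
  }

  labels <- max.col(tau, ties.method = "first")
  # the Poisson-on-binary likelihood makes the posterior mean rate an
  # estimate of the presence PROBABILITY; report edge_rate on the
  # generative truncated-Poisson scale (-log(1 - p), the same inverse link
  # modular_as_generative uses) so sampled networks reproduce the fitted
  # edge density
  p_hat <- pmin(P$a_th / P$b_th, 1 - 1e-9)
  params <- wsbm_params(edge_rate = -log(1 - p_hat),
                        weight_mean = P$m_q,
                        weight_var = P$b_ng / P$a_ng)
  structure(list(
    responsibilities = tau, params = params, log_evidence = bound,
    map_partition = partition(labels, k = k), elbo_trace = trace,
    converged = converged, k = as.integer(k), alpha = alpha,
    seed = seed), class = "wsbm_fit")
}

#' @export
print.wsbm_fit <- function(x, ...) {
  cat(sprintf("<wsbm_fit> k = %d, log-evidence = %.4f, %s after %d sweeps\n",
              x$k, x$log_evidence,
              if (x$converged) "converged" else "NOT converged",
              length(x$elbo_trace) - 1))
  invisible(x)
}

#' Variational lower bound of a fitted model
#'
#' The stored evidence lower bound (nats); invariant under permutation of
#' block labels. Differences of these bounds across fits are used as
#' Bayes-factor approximations for model comparison.
#'
#' @param post a `wsbm_fit`
#' @return scalar log-evidence
#' @export
log_evidence <- function(post) {
  stopifnot(inherits(post, "wsbm_fit"))
  post$log_evidence
}

#' Sample a network from WSBM block parameters
#'
#' Per node pair, presence is Poisson(edge_rate) truncated to existence
#' (count >= 1); existing edges draw Normal(weight_mean, weight_var) weights
#' clipped at `floor`.
#'
#' @param params `wsbm_params`
#' @param p `partition` with `k` matching the parameter dimension
#' @param seed RNG seed
#' @param floor positive weight clip floor
#' @param nodes optional node metadata to attach
#' @return a `connectome`
#' @export
sample_network <- function(params, p, seed = 1L, floor = 1e-6, nodes = NULL) {
  stopifnot(inherits(params, "wsbm_params"))
  labels <- part_labels(p)
  if (part_k(p) != params$k) stop("partition k does not match params dimension")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  W <- .sample_block_network(params$edge_rate, params$weight_mean,
                             sqrt(params$weight_var), labels, floor)
  connectome(W, nodes = nodes)
}

#' Complete-data log-likelihood under a hard partition
#'
#' The alpha-weighted sum over all unordered node pairs of the Poisson
#' edge-existence log-density and (for present edges) the Normal edge-weight
#' log-density. Used for oracle checks of the inference likelihood term.
#'
#' @param A `connectome` or matrix
#' @param p `partition`
#' @param params `wsbm_params`
#' @param alpha likelihood mixing weight
#' @return scalar log-likelihood (nats)
#' @export
complete_loglik <- function(A, p, params, alpha = 0.5) {
  W <- conn_weights(A)
  labels <- part_labels(p)
  n <- nrow(W)
  iu <- which(upper.tri(W))
  bi <- labels[row(W)[iu]]; bj <- labels[col(W)[iu]]
  th <- params$edge_rate[cbind(bi, bj)]
  mu <- params$weight_mean[cbind(bi, bj)]
  s2 <- params$weight_var[cbind(bi, bj)]
  x <- (W[iu] > 0) * 1
  w <- W[iu]
  pois <- x * log(pmax(th, 1e-300)) - th  # x in {0,1}: log(x!) = 0
  norm <- ifelse(x > 0, -0.5 * log(2 * pi * s2) - (w - mu)^2 / (2 * s2), 0)
  sum(alpha * pois + (1 - alpha) * norm)
}
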