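# Block-interaction strength extraction and age-trend inference: linear,
# quadratic and Poisson-curve regressions after nuisance residualization,
# leave-one-out cross-validation (uncentered R^2), permutation p-values,
# Bonferroni control, and block-vector similarity trends.

#' Community block matrix of a subject
#'
#' Entry (i, j) summarises the edge weights running between communities i
#' and j: their total (each undirected edge counted once, including within
#' blocks) or their mean over all node pairs of the block pair (mitigating
#' community-size effects). In total mode the upper-triangle-plus-diagonal
#' sums exactly to the subject's total network strength.
#'
#' @param A `connectome` or matrix
#' @param p `partition`
#' @param mode `"total"` or `"mean"`
#' @return object of class `block_matrix`: `values` (k x k symmetric),
#'   `mode`, `k`
#' @export
block_summary <- function(A, p, mode = c("total", "mean")) {
  mode <- match.arg(mode)
  W <- conn_weights(A)
  lab <- part_labels(p)
  k <- part_k(p)
  Z <- matrix(0, length(lab), k)
  Z[cbind(seq_along(lab), lab)] <- 1
  tot <- crossprod(Z, W %*% Z)       # ordered sums; diagonal double-counts
  diag(tot) <- diag(tot) / 2
  tot[upper.tri(tot)] <- t(tot)[upper.tri(tot)]  # enforce exact symmetry
  tot[lower.tri(tot)] <- t(tot)[lower.tri(tot)]
  if (mode == "mean") {
    sizes <- tabulate(lab, nbins = k)
    npairs <- outer(sizes, sizes)
    diag(npairs) <- sizes * (sizes - 1) / 2
    vals <- ifelse(npairs > 0, tot / npairs, 0)
  } else {
    vals <- tot
  }
  structure(list(values = vals, mode = mode, k = k), class = "block_matrix")
}

#' Consensus-model block vector
#'
#' Unrolls a k x k community-interaction summary into the fixed
#' upper-triangle-plus-diagonal ordering of [block_pairs()]. For a fitted
#' WSBM (`wsbm_params`) the entries are the elementwise product of the
#' predicted mean edge weight and the predicted edge-existence probability
#' `1 - exp(-rate)`; for a `block_matrix` (e.g. the empirical mean-strength
#' matrix under a modular fit) the stored values are unrolled directly.
#'
#' @param source a `wsbm_params`, `block_matrix`, or plain k x k matrix
#' @return numeric block vector of length `(k^2 - k)/2 + k`
#' @export
consensus_vector <- function(source) {
  if (inherits(source, "wsbm_params")) {
    unroll_blocks(source$weight_mean * (1 - exp(-source$edge_rate)))
  } else if (inherits(source, "block_matrix")) {
    unroll_blocks(source$values)
  } else {
    unroll_blocks(as.matrix(source))
  }
}

#' Residualize a response on nuisance covariates
#'
#' OLS residuals of `y` on `[1, G]`. With `G = NULL` this is mean-centering.
#'
#' @param y response vector
#' @param G n x q nuisance covariate matrix (or NULL)
#' @return residual vector
#' @export
residualize <- function(y, G = NULL) {
  if (is.null(G) || NCOL(G) == 0) return(y - mean(y))
  X <- cbind(1, as.matrix(G))
  as.numeric(y - X %*% qr.coef(qr(X), y))
}

# OLS with leave-one-out machinery via the hat matrix
.ols_loo <- function(X, y) {
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  fit <- as.numeric(X %*% beta)
  e <- y - fit
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  h <- pmin(h, 1 - 1e-10)
  list(coef = beta, fitted = fit, resid = e, sse = sum(e^2),
       h = h, loo_pred = y - e / (1 - h))
}

.poisson_grid <- function() exp(seq(log(1e-3), log(1), length.out = 16))

.design <- function(age, model, beta2 = NULL) {
  switch(model,
    linear = cbind(1, age),
    quadratic = cbind(1, age, age^2),
    poisson_curve = cbind(1, age * exp(-beta2 * age)),
    stop("unknown model: ", model))
}

#' Fit one age-trend regression model
#'
#' Three model families for a (residualized) block strength `y` against
#' age: linear `b0 + b1*age`, quadratic `b0 + b1*age + b2*age^2`, and the
#' Poisson curve `b0 + b1*age*exp(-b2*age)`. Linear/quadratic use OLS; the
#' Poisson curve profiles `b2` over a 16-point log-spaced grid in
#' `[1e-3, 1]` and refines the best grid point by 1-D optimisation (OLS on
#' the induced regressor at each candidate). Leave-one-out predictions are
#' exact for the OLS families (hat-matrix identity); for the Poisson curve
#' the shape parameter is re-selected per fold from the grid via SSE
#' downdates (documented numerical choice).
#'
#' @param y response vector (finite)
#' @param age age vector (years)
#' @param model `"linear"`, `"quadratic"` or `"poisson_curve"`
#' @return object of class `mlr_fit`: `model`, `coef` (named beta0..beta2),
#'   `fitted`, `residuals`, `loocv_rmse`, `loocv_r2` (uncentered, may be
#'   negative), `perm_p` (NA until [perm_pvalue()] is run)
#' @export
fit_trend <- function(y, age, model = c("linear", "quadratic", "poisson_curve")) {
  model <- match.arg(model)
  if (!all(is.finite(y)) || !all(is.finite(age))) stop("non-finite inputs")
  n <- length(y)
  stopifnot(length(age) == n, n >= 4)
  if (model %in% c("linear", "quadratic")) {
    o <- .ols_loo(.design(age, model), y)
    coefs <- o$coef
    names(coefs) <- c("beta0", "beta1", if (model == "quadratic") "beta2")
    loo <- o$loo_pred
    fitted <- o$fitted
  } else {
    grid <- .poisson_grid()
    fits <- lapply(grid, function(b2) .ols_loo(.design(age, model, b2), y))
    sses <- vapply(fits, `[[`, numeric(1), "sse")
    gi <- which.min(sses)
    lo <- grid[max(1, gi - 1)]; hi <- grid[min(length(grid), gi + 1)]
    b2 <- optimize(function(b2) .ols_loo(.design(age, model, b2), y)$sse,
                   interval = c(lo, hi))$minimum
    refined <- .ols_loo(.design(age, model, b2), y)
    best <- if (refined$sse <= sses[gi]) refined else fits[[gi]]
    if (refined$sse > sses[gi]) b2 <- grid[gi]
    coefs <- c(beta0 = unname(best$coef[1]), beta1 = unname(best$coef[2]),
               beta2 = b2)
    fitted <- best$fitted
    # grid-restricted per-fold re-selection of the shape parameter
    loosse <- vapply(fits, function(f) f$sse - f$resid^2 / (1 - f$h),
                     numeric(n))
    pick <- max.col(-loosse, ties.method = "first")
    loo <- vapply(seq_len(n), function(i) fits[[pick[i]]]$loo_pred[i],
                  numeric(1))
  }
  loo_res <- y - loo
  denom <- sum(y^2)
  structure(list(
    model = model, coef = coefs, fitted = fitted, residuals = y - fitted,
    loocv_rmse = sqrt(mean(loo_res^2)),
    loocv_r2 = if (denom > 0) 1 - sum(loo_res^2) / denom else NA_real_,
    perm_p = NA_real_), class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, ...) {
  cat(sprintf("<mlr_fit> %s: %s | LOOCV RMSE %.4g, R2 %.3f%s\n",
              x$model,
              paste(sprintf("%s=%.4g", names(x$coef), x$coef), collapse = ", "),
              x$loocv_rmse, x$loocv_r2,
              if (is.na(x$perm_p)) "" else sprintf(", p = %.4g", x$perm_p)))
  invisible(x)
}

#' Leave-one-out score of a trend model
#'
#' LOO predictions as in [fit_trend()]; returns the RMSE and the uncentered
#' coefficient of determination `R^2 = 1 - sum((y - y')^2) / sum(y^2)`
#' (denominator the raw sum of squares, not centered; can be negative and
#' is not clamped).
#'
#' @inheritParams fit_trend
#' @return named vector `c(rmse, r2)`
#' @export
loocv_score <- function(y, age, model) {
  f <- fit_trend(y, age, model)
  c(rmse = f$loocv_rmse, r2 = f$loocv_r2)
}

#' Select the best trend family by LOOCV error
#'
#' Fits all three families and returns the one with the lowest LOOCV RMSE.
#' Ties and near-ties go to the simpler model (linear < quadratic <
#' poisson_curve by parameter count): a more complex family must improve
#' LOOCV RMSE by more than a relative margin (`rel_tol`, default 2%) to be
#' chosen. The margin is needed because the Poisson curve nests a
#' near-linear shape as its decay rate approaches zero, so raw LOOCV
#' comparisons between genuinely equivalent fits reduce to noise.
#'
#' @inheritParams fit_trend
#' @param rel_tol relative LOOCV-RMSE margin a more complex model must beat
#' @return the winning `mlr_fit`
#' @export
select_trend <- function(y, age, rel_tol = 0.02) {
  models <- c("linear", "quadratic", "poisson_curve")
  fits <- lapply(models, function(m) fit_trend(y, age, m))
  rmses <- vapply(fits, `[[`, numeric(1), "loocv_rmse")
  best <- 1L
  for (m in 2:3) {
    if (rmses[m] < rmses[best] * (1 - rel_tol)) best <- m
  }
  fits[[best]]
}

#' Permutation p-value for an age trend
#'
#' Permutes age across `n_perm` refits of the already-selected model family
#' (model selection is not re-run per permutation) and compares the LOOCV
#' R^2 statistic to the observed one:
#' `p = (1 + #(perm >= obs)) / (1 + n_perm)`.
#'
#' @inheritParams fit_trend
#' @param n_perm permutation count (default 10000)
#' @param seed RNG seed
#' @return p-value in `(0, 1]`
#' @export
perm_pvalue <- function(y, age, model, n_perm = 10000L, seed = 1L) {
  obs <- loocv_score(y, age, model)["r2"]
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    r2 <- loocv_score(y, sample(age), model)["r2"]
    if (!is.na(r2) && r2 >= obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Bonferroni mask over a family of p-values
#'
#' Threshold `0.05 / m`; the reported alpha is rounded to one significant
#' figure (so m = 55 reports 0.0009 and m = 114 reports 0.0004) while the
#' mask itself uses the exact threshold.
#'
#' @param pvals numeric p-values
#' @param m family size (default `length(pvals)`)
#' @return list: `mask` (logical), `alpha` (exact threshold),
#'   `alpha_reported` (one significant figure)
#' @export
bonferroni_mask <- function(pvals, m = length(pvals)) {
  stopifnot(m >= 1)
  alpha <- 0.05 / m
  list(mask = pvals < alpha, alpha = alpha,
       alpha_reported = signif(alpha, 1))
}

#' Cosine similarity and city-block distance between block vectors
#'
#' @param v,ref numeric vectors of equal length
#' @return named vector `c(cosine, cityblock)`
#' @export
vector_similarity <- function(v, ref) {
  stopifnot(length(v) == length(ref))
  c(cosine = sum(v * ref) / (sqrt(sum(v^2)) * sqrt(sum(ref^2))),
    cityblock = sum(abs(v - ref)))
}

#' End-to-end lifespan trend analysis
#'
#' For every block pair: collects the total-strength vector across subjects,
#' residualizes it on the nuisance covariates (sex and total strength by
#' default, motion optionally), selects the best trend family by LOOCV,
#' computes a permutation p-value, and applies a Bonferroni mask over the
#' `l = (k^2 - k)/2 + k` comparisons. Separately, each subject's
#' mean-strength block vector is compared to the consensus vector (cosine /
#' city-block) and the same regression machinery is applied to the
#' similarity measures against age.
#'
#' @param cohort result of [generate_cohort()], or a list with `subjects`
#'   (each holding a `connectome`) and `table` (age, sex, motion,
#'   total_strength)
#' @param partitions a single `partition` used for all subjects, or a list
#'   of per-subject (aligned) partitions
#' @param consensus_vec reference block vector (see [consensus_vector()])
#' @param include_motion add motion to the nuisance set (default FALSE)
#' @param n_perm permutations per test (default 1000; scale to taste)
#' @param seed RNG seed
#' @return list: `block_trends` (data.frame: block_i, block_j, model,
#'   beta0..beta2, loocv_rmse, loocv_r2, p, significant), `similarity`
#'   (per-subject cosine/cityblock), `similarity_trends` (same fit columns
#'   for cosine and cityblock vs age)
#' @export
lifespan_pipeline <- function(cohort, partitions, consensus_vec,
                              include_motion = FALSE, n_perm = 1000L,
                              seed = 1L) {
  subjects <- cohort$subjects
  tab <- cohort$table
  ns <- length(subjects)
  if (inherits(partitions, "partition")) {
    partitions <- replicate(ns, partitions, simplify = FALSE)
  }
  stopifnot(length(partitions) == ns)
  k <- part_k(partitions[[1]])
  bp <- block_pairs(k)
  G <- cbind(sex = tab$sex, total_strength = tab$total_strength)
  if (include_motion) G <- cbind(G, motion = tab$motion)
  age <- tab$age

  totals <- vapply(seq_len(ns), function(si) {
    unroll_blocks(block_summary(subjects[[si]]$connectome,
                                partitions[[si]], "total")$values)
  }, numeric(nrow(bp)))
  means <- vapply(seq_len(ns), function(si) {
    unroll_blocks(block_summary(subjects[[si]]$connectome,
                                partitions[[si]], "mean")$values)
  }, numeric(nrow(bp)))

  seeds <- .trial_seeds(seed, nrow(bp) + 2L)
  fit_row <- function(y, sd_seed) {
    r <- residualize(y, G)
    f <- select_trend(r, age)
    p <- perm_pvalue(r, age, f$model, n_perm = n_perm, seed = sd_seed)
    data.frame(model = f$model,
               beta0 = unname(f$coef["beta0"]),
               beta1 = unname(f$coef["beta1"]),
               beta2 = if ("beta2" %in% names(f$coef))
                 unname(f$coef["beta2"]) else NA_real_,
               loocv_rmse = f$loocv_rmse, loocv_r2 = f$loocv_r2, p = p)
  }
  rows <- lapply(seq_len(nrow(bp)), function(r) {
    cbind(data.frame(block_i = bp$i[r], block_j = bp$j[r]),
          fit_row(totals[r, ], seeds[r]))
  })
  block_trends <- do.call(rbind, rows)
  bon <- bonferroni_mask(block_trends$p, m = nrow(bp))
  block_trends$significant <- bon$mask

  sim <- t(vapply(seq_len(ns), function(si) {
    vector_similarity(means[, si], consensus_vec)
  }, numeric(2)))
  similarity <- data.frame(subject = tab$id, cosine = sim[, 1],
                           cityblock = sim[, 2])
  strends <- rbind(
    cbind(data.frame(measure = "cosine"),
          fit_row(similarity$cosine, seeds[nrow(bp) + 1L])),
    cbind(data.frame(measure = "cityblock"),
          fit_row(similarity$cityblock, seeds[nrow(bp) + 2L])))

  list(block_trends = block_trends, similarity = similarity,
       similarity_trends = strends,
       bonferroni = bon[c("alpha", "alpha_reported")])
}
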