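test_that("block summaries obey hand sums and the conservation identity", {
  # 4-node, 2-block toy with listed weights
  W <- matrix(0, 4, 4)
  W[1, 2] <- 0.5; W[1, 3] <- 0.2; W[1, 4] <- 0.1; W[2, 3] <- 0.4
  W <- W + t(W)
  p <- partition(c(1, 1, 2, 2))
  bs <- block_summary(W, p, "total")$values
  expect_equal(bs[1, 1], 0.5)          # edge 1-2
  expect_equal(bs[1, 2], 0.2 + 0.1 + 0.4)
  expect_equal(bs[2, 2], 0)
  bm <- block_summary(W, p, "mean")$values
  expect_equal(bm[1, 1], 0.5)          # one within pair
  expect_equal(bm[1, 2], 0.7 / 4)      # four cross pairs

  # one community: single entry equals total strength
  one <- block_summary(W, partition(rep(1, 4)), "total")$values
  expect_equal(as.numeric(one), total_strength(W))

  set.seed(27)
  for (rep in 1:5) {
    A <- rand_connectome(12, coords = FALSE)
    q <- rand_partition(12, 4)
    tot <- block_summary(A, q, "total")$values
    expect_equal(sum(unroll_blocks(tot)), total_strength(A), tolerance = 1e-10)
    expect_equal(tot, t(tot))
  }
})

test_that("consensus vectors unroll parameters and empirical block matrices", {
  # rates large (presence ~ 1), means all m: constant vector m
  params <- wsbm_params(matrix(50, 3, 3), matrix(0.4, 3, 3),
                        matrix(0.1, 3, 3))
  expect_equal(consensus_vector(params), rep(0.4, 6), tolerance = 1e-6)

  # k = 2 toy: elementwise product against a hand computation
  rate <- matrix(c(1, 0.2, 0.2, 0.5), 2)
  mu <- matrix(c(0.3, 0.1, 0.1, 0.2), 2)
  pp <- wsbm_params(rate, mu, matrix(0.1, 2, 2))
  want <- c(0.3 * (1 - exp(-1)), 0.1 * (1 - exp(-0.2)), 0.2 * (1 - exp(-0.5)))
  expect_equal(consensus_vector(pp), want)

  expect_length(consensus_vector(wsbm_params(matrix(1, 10, 10),
                                             matrix(1, 10, 10),
                                             matrix(1, 10, 10))), 55)
})

test_that("residualization matches the normal equations", {
  set.seed(28)
  y <- rnorm(30)
  expect_equal(residualize(y, NULL), y - mean(y))

  G <- cbind(rnorm(30), rnorm(30))
  r <- residualize(y, G)
  X <- cbind(1, G)
  want <- as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
  expect_equal(r, want, tolerance = 1e-10)

  # y exactly linear in G: residuals ~ 0
  y2 <- 2 + 3 * G[, 1] - G[, 2]
  expect_equal(residualize(y2, G), rep(0, 30), tolerance = 1e-10)
})

test_that("trend fits recover exact and noisy planted parameters", {
  age <- seq(6, 85, length.out = 50)
  f <- fit_trend(2 + 3 * age, age, "linear")
  expect_equal(unname(f$coef), c(2, 3), tolerance = 1e-8)

  fq <- fit_trend(1 + 0.5 * age - 0.01 * age^2, age, "quadratic")
  expect_equal(unname(fq$coef), c(1, 0.5, -0.01), tolerance = 1e-6)

  # poisson curve value at age 0 equals beta0
  fp <- fit_trend(0.2 + 0.8 * age * exp(-0.05 * age), age, "poisson_curve")
  pred0 <- fp$coef["beta0"] + fp$coef["beta1"] * 0 * exp(-fp$coef["beta2"] * 0)
  expect_equal(unname(pred0), unname(fp$coef["beta0"]))

  # recovery at n = 300 with noise sd 10% of range
  set.seed(29)
  age3 <- runif(300, 6, 85)
  truth <- c(b0 = 0.3, b1 = 0.06, b2 = 0.04)
  y3 <- truth["b0"] + truth["b1"] * age3 * exp(-truth["b2"] * age3)
  y3 <- y3 + rnorm(300, 0, 0.1 * diff(range(y3)))
  fr <- fit_trend(y3, age3, "poisson_curve")
  expect_lt(abs(fr$coef["beta1"] - truth["b1"]) / truth["b1"], 0.10)
  expect_lt(abs(fr$coef["beta2"] - truth["b2"]) / truth["b2"], 0.25)

  expect_error(fit_trend(c(1, NA, 3, 4, 5), 1:5, "linear"), "non-finite")
})

test_that("LOOCV uses the uncentered R2 exactly as defined", {
  set.seed(30)
  age <- seq(10, 80, length.out = 12)
  y <- 1 + 0.2 * age + rnorm(12, 0, 0.5)

  # hand-rolled LOO loop oracle (linear model)
  loo <- sapply(seq_along(y), function(i) {
    fit <- lm(yy ~ aa, data.frame(yy = y[-i], aa = age[-i]))
    predict(fit, data.frame(aa = age[i]))
  })
  want_rmse <- sqrt(mean((y - loo)^2))
  want_r2 <- 1 - sum((y - loo)^2) / sum(y^2)
  got <- loocv_score(y, age, "linear")
  expect_equal(unname(got["rmse"]), want_rmse, tolerance = 1e-10)
  expect_equal(unname(got["r2"]), want_r2, tolerance = 1e-10)

  # y != 0 but predictions can be poor: uncentered R2 may go negative
  ybad <- rep(c(-1, 1), 6)
  expect_lt(loocv_score(ybad, age, "linear")["r2"], 1)
})

test_that("model selection is consistent and ties favour simplicity", {
  set.seed(31)
  age <- runif(120, 6, 85)
  lin_wins <- 0; quad_wins <- 0
  for (b in 1:40) {
    yl <- 1 + 0.05 * age + rnorm(120, 0, 0.3)
    if (select_trend(yl, age)$model == "linear") lin_wins <- lin_wins + 1
    yq <- 2 + 0.1 * age - 0.0012 * age^2 + rnorm(120, 0, 0.08)
    if (select_trend(yq, age)$model == "quadratic") quad_wins <- quad_wins + 1
  }
  expect_gte(lin_wins / 40, 0.9)
  expect_gte(quad_wins / 40, 0.9)

  # degenerate constant y: tie rule returns the linear model
  expect_equal(select_trend(rep(1, 20), seq_len(20))$model, "linear")
})

test_that("permutation p-values hit bounds and are deterministic", {
  age <- seq(6, 85, length.out = 40)
  y <- 0.5 + 0.03 * age  # perfectly age-determined
  p <- perm_pvalue(y, age, "linear", n_perm = 99, seed = 1)
  expect_equal(p, 1 / 100)
  expect_identical(perm_pvalue(y, age, "linear", n_perm = 50, seed = 9),
                   perm_pvalue(y, age, "linear", n_perm = 50, seed = 9))
})

test_that("Bonferroni reporting matches the printed conventions", {
  b55 <- bonferroni_mask(runif(55), 55)
  expect_equal(b55$alpha_reported, 9e-4)
  expect_equal(bonferroni_mask(runif(114), 114)$alpha_reported, 4e-4)
  expect_equal(bonferroni_mask(0.04, 1)$alpha, 0.05)
  expect_true(bonferroni_mask(0.04, 1)$mask)
})

test_that("vector similarity has the documented extremes and oracle", {
  v <- c(1, 2, 3)
  expect_equal(unname(vector_similarity(v, v)), c(1, 0))
  expect_equal(unname(vector_similarity(v, -v)["cosine"]), -1)
  set.seed(32)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(unname(vector_similarity(a, b)["cosine"]),
               sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  expect_equal(unname(vector_similarity(a, b)["cityblock"]), sum(abs(a - b)))
})

test_that("the lifespan pipeline flags a planted quadratic pair", {
  # the trended block must stay a small share of total strength, otherwise
  # residualizing on the total-strength nuisance removes the signal itself
  k <- 4
  spec <- set_trend(make_trend_spec(k), k, 1, 1, trend_quadratic(45, 0.12))
  rate <- matrix(0.3, k, k); diag(rate) <- 2
  rate[1, 1] <- 4  # near-certain presence keeps block-sum noise low
  mu <- matrix(0.1, k, k); diag(mu) <- 0.5
  cfg <- cohort_config(80, n_nodes = 40, k_planted = k,
                       edge_rate_matrix = rate, weight_mean_matrix = mu,
                       weight_sd_matrix = matrix(0.05, k, k),
                       trend_spec = spec, rng_seed = 33)
  ch <- generate_cohort(cfg)
  cv <- consensus_vector(block_summary(ch$subjects[[1]]$connectome,
                                       ch$truth, "mean"))
  res <- lifespan_pipeline(ch, ch$truth, cv, n_perm = 499, seed = 2)
  expect_equal(nrow(res$block_trends), 10)
  r11 <- res$block_trends[res$block_trends$block_i == 1 &
                            res$block_trends$block_j == 1, ]
  expect_equal(r11$model, "quadratic")
  expect_true(r11$significant)

  # determinism given seeds
  res2 <- lifespan_pipeline(ch, ch$truth, cv, n_perm = 499, seed = 2)
  expect_identical(res$block_trends, res2$block_trends)
  expect_equal(nrow(res$similarity), 80)
})
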