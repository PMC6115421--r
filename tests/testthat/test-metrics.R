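test_that("participation coefficient matches its direct-sum oracle", {
  cl <- make_cliques(c(4, 4))
  p <- partition(cl$labels)
  expect_equal(participation_coefficient(cl$W, p), rep(0, 8))

  # weight split equally over 2 communities: 1 - 2 (1/2)^2 = 0.5
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[1, 3] <- W[3, 1] <- 1
  expect_equal(participation_coefficient(W, partition(c(1, 1, 2)))[1], 0.5)

  set.seed(17)
  A <- rand_connectome(10, coords = FALSE)
  q <- rand_partition(10, 3)
  got <- participation_coefficient(A, q)
  for (i in 1:10) {
    wi <- sum(A$weights[i, ])
    want <- 1 - sum(sapply(1:part_k(q), function(s) {
      (sum(A$weights[i, q$labels == s]) / wi)^2
    }))
    expect_equal(got[i], want, tolerance = 1e-12)
  }
  expect_true(all(got >= 0 & got <= 1))
})

test_that("within-module z-score standardises within communities", {
  set.seed(18)
  A <- rand_connectome(8, coords = FALSE)
  q <- partition(c(1, 1, 1, 1, 2, 2, 2, 3))  # includes a singleton
  z <- within_module_z(A, q)
  expect_equal(z[8], 0)                      # singleton rule
  for (s in 1:2) {
    idx <- which(q$labels == s)
    kappa <- sapply(idx, function(i) sum(A$weights[i, idx]))
    expect_equal(z[idx], (kappa - mean(kappa)) / sd(kappa), tolerance = 1e-12)
    expect_equal(mean(z[idx]), 0, tolerance = 1e-12)
  }
})

test_that("node assortativity contributions sum to the global coefficient", {
  set.seed(19)
  A <- rand_connectome(12, coords = FALSE)
  contrib <- node_assortativity(A)
  expect_equal(sum(contrib), attr(contrib, "global"), tolerance = 1e-8)

  # star graph: globally disassortative
  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star <- star + t(star)
  expect_lt(attr(node_assortativity(star), "global"), 0)

  # two homogeneous cliques: positive community values
  cl <- make_cliques(c(5, 4), within = 1, between = 0)
  ca <- community_assortativity(cl$W, partition(cl$labels))
  expect_true(all(is.finite(ca)))
})

test_that("laterality KS hits its documented extremes", {
  hemi <- rep(c("L", "R"), each = 5)
  expect_equal(laterality_ks(rep(c(1, 2, 3, 4, 5), 2), hemi), 0)
  expect_equal(laterality_ks(c(1:5, 11:15), hemi), 1)
  set.seed(20)
  v <- rnorm(10)
  expect_equal(laterality_ks(v, hemi), ks_oracle(v[1:5], v[6:10]))
})

test_that("compactness sums within-community pairwise distances", {
  co <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(compactness(partition(c(1, 1)), co), 3)
  expect_equal(compactness(partition(c(1, 1)), rbind(c(1, 1, 1), c(1, 1, 1))), 0)
  set.seed(21)
  co6 <- rand_coords(6)
  p <- partition(c(1, 1, 2, 2, 2, 1))
  D <- as.matrix(dist(co6))
  want <- 0
  for (s in 1:2) {
    idx <- which(p$labels == s)
    for (a in idx) for (b in idx) if (a < b) want <- want + D[a, b]
  }
  expect_equal(compactness(p, co6), want, tolerance = 1e-12)
})

test_that("ICC(3,1) matches ANOVA arithmetic and its extremes", {
  M <- matrix(c(2, 4, 6,
                2.5, 4.5, 5.5,
                1.5, 4, 6.5), nrow = 3)  # 3 communities x 3 subjects
  expect_equal(icc31(M), icc31_aov_oracle(M), tolerance = 1e-10)

  same <- matrix(rep(c(1, 5, 9), 4), nrow = 3)
  expect_equal(icc31(same), 1)

  set.seed(22)
  M2 <- matrix(rnorm(8 * 6), 8, 6)
  expect_equal(icc31(M2), icc31_aov_oracle(M2), tolerance = 1e-10)
})

test_that("high-degree dispersion ICC separates consistent from shuffled", {
  # a hub community is needed: with exchangeable blocks the top-degree set
  # is uniform over communities and there is nothing for ICC to detect
  set.seed(23)
  k <- 4
  p <- matrix(0.15, k, k); diag(p) <- 0.5
  p[1, ] <- p[, 1] <- 0.6; p[1, 1] <- 0.9
  mu <- matrix(0.1, k, k); diag(mu) <- 0.3
  mu[1, ] <- mu[, 1] <- 0.35; mu[1, 1] <- 0.5
  cfg <- cohort_config(8, n_nodes = 40, k_planted = k,
                       edge_rate_matrix = -log(1 - p),
                       weight_mean_matrix = mu,
                       weight_sd_matrix = matrix(0.05, k, k), rng_seed = 37)
  ch <- generate_cohort(cfg)
  nets <- lapply(ch$subjects, `[[`, "connectome")
  parts <- replicate(8, ch$truth, simplify = FALSE)
  res <- top_degree_dispersion_icc(parts, nets, n_boot = 100, seed = 1)
  expect_equal(dim(res$counts), c(4, 8))
  expect_equal(colSums(res$counts), rep(10, 8))  # ceiling(0.25 * 40)
  expect_gt(res$icc, 0.3)

  # independently shuffled counts: ICC near 0, CI covers 0
  shuffled <- lapply(1:8, function(i) partition(sample(ch$truth$labels), 4))
  res0 <- top_degree_dispersion_icc(shuffled, nets, n_boot = 200, seed = 2)
  expect_lt(res0$icc, res$icc)
  expect_true(res0$ci[1] <= 0.25)
})

test_that("versatility is the entropy of aligned assignment frequencies", {
  M <- matrix(1L, 5, 6)  # constant: zero versatility
  expect_equal(versatility(M, align = FALSE), rep(0, 5))

  spread <- matrix(rep(1:4, 2), nrow = 1)  # uniform over 4 blocks
  expect_equal(versatility(spread, align = FALSE), log(4))

  set.seed(24)
  M2 <- matrix(sample(1:3, 4 * 5, replace = TRUE), 4, 5)
  got <- versatility(M2, align = FALSE)
  want <- apply(M2, 1, function(r) {
    f <- table(r) / length(r)
    -sum(f * log(f))
  })
  expect_equal(got, unname(want), tolerance = 1e-12)
  expect_true(all(got <= log(3) + 1e-12))

  # alignment removes pure relabelings before the entropy
  base <- c(1L, 1L, 2L, 2L, 3L, 3L)
  Mal <- cbind(base, c(2L, 2L, 3L, 3L, 1L, 1L), c(3L, 3L, 1L, 1L, 2L, 2L))
  expect_equal(versatility(Mal), rep(0, 6))
})

test_that("versatility differences are null when methods agree", {
  set.seed(25)
  M <- matrix(sample(1:3, 6 * 8, replace = TRUE), 6, 8)
  res <- versatility_difference_test(M, M, n_perm = 50, seed = 1)
  expect_equal(res$difference, rep(0, 6))
  expect_true(all(res$p > 0.9))
  expect_false(any(res$significant))

  # permuting subject order leaves observed differences unchanged
  M2 <- matrix(sample(1:3, 6 * 8, replace = TRUE), 6, 8)
  r1 <- versatility_difference_test(M, M2, n_perm = 10, seed = 1)
  perm <- sample(8)
  r2 <- versatility_difference_test(M[, perm], M2[, perm], n_perm = 10,
                                    seed = 1,
                                    reference = partition(M[, 1], 3))
  r1b <- versatility_difference_test(M, M2, n_perm = 10, seed = 1,
                                     reference = partition(M[, 1], 3))
  expect_equal(r2$difference, r1b$difference, tolerance = 1e-12)
})

test_that("versatility permutation test is calibrated under the null", {
  # columns drawn from one pool: type-I rate at alpha = 0.05 within
  # binomial bounds (scaled-down version of the stated calibration)
  # enough subjects are needed to de-discretise the entropy statistic;
  # tiny matrices make the permutation test exact-but-conservative
  set.seed(26)
  n_sets <- 120
  hits <- 0; tests <- 0
  for (b in seq_len(n_sets)) {
    pool <- matrix(sample(1:3, 8 * 40, replace = TRUE), 8, 40)
    A <- pool[, 1:20]; B <- pool[, 21:40]
    res <- versatility_difference_test(A, B, n_perm = 99, seed = b,
                                       reference = partition(pool[, 1], 3))
    node <- 1  # one pre-registered node per dataset keeps tests independent
    hits <- hits + (res$p[node] <= 0.05)
    tests <- tests + 1
  }
  ci <- binom.test(hits, tests, 0.05)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})
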