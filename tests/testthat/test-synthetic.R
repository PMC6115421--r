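test_that("planted bilateral partitions pair homotopic nodes", {
  # smallest bilateral case: L = {1, 2}, R = {3, 4}, partners i <-> i + n/2
  p <- make_planted_partition(4, 2, bilateral = TRUE)
  expect_equal(p$labels, c(1L, 2L, 1L, 2L))

  p10 <- make_planted_partition(114, 10, sizes = c(3, 4, 5, 5, 6, 6, 6, 7, 7, 8))
  sizes <- tabulate(p10$labels, 10)
  expect_true(all(sizes > 0))
  expect_true(all(sizes >= 6 & sizes <= 21))
  # homotopic partners share a block; both hemispheres in every block
  expect_equal(p10$labels[1:57], p10$labels[58:114])

  expect_equal(unique(make_planted_partition(8, 1)$labels), 1L)
  expect_error(make_planted_partition(4, 8), "invalid")
  expect_error(make_planted_partition(10, 6, bilateral = TRUE), "invalid")
})

test_that("subject sampling respects degenerate rate configurations", {
  k <- 2
  zero <- cohort_config(1, n_nodes = 8, k_planted = k,
                        edge_rate_matrix = matrix(0, k, k),
                        weight_mean_matrix = matrix(1, k, k),
                        weight_sd_matrix = matrix(0.1, k, k))
  s <- sample_subject(zero, age = 30, seed = 1)
  expect_equal(sum(s$connectome$weights), 0)

  sep <- cohort_config(1, n_nodes = 8, k_planted = k,
                       edge_rate_matrix = diag(2) * 50,  # presence ~ 1 within
                       weight_mean_matrix = matrix(1, k, k),
                       weight_sd_matrix = matrix(0.01, k, k))
  s2 <- sample_subject(sep, age = 30, seed = 1)
  X <- s2$connectome$weights > 0
  lab <- s2$true_partition$labels
  expect_true(all(X[lab == 1, lab == 1][upper.tri(diag(4))]))
  expect_true(all(!X[lab == 1, lab == 2]))

  expect_equal(s2$total_strength, total_strength(s2$connectome))
})

test_that("empirical presence converges to the truncated-Poisson probability", {
  # rate 0.5 on >= 10,000 node pairs: density within 3 SE of 1 - exp(-0.5)
  k <- 1
  n <- 142  # 10,011 pairs
  cfg <- cohort_config(1, n_nodes = n, k_planted = k,
                       edge_rate_matrix = matrix(0.5, 1, 1),
                       weight_mean_matrix = matrix(1, 1, 1),
                       weight_sd_matrix = matrix(0.1, 1, 1))
  s <- sample_subject(cfg, age = 30, seed = 42)
  p_true <- 1 - exp(-0.5)
  npairs <- n * (n - 1) / 2
  se <- sqrt(p_true * (1 - p_true) / npairs)
  expect_lt(abs(edge_density(s$connectome) - p_true), 3 * se)
})

test_that("cohort generation is reproducible and validates its config", {
  expect_error(default_cohort_config(n_subjects = 0), "invalid")
  expect_error(cohort_config(5, n_nodes = 8, k_planted = 2,
                             edge_rate_matrix = matrix(c(0, 1, 0.5, 0), 2),
                             weight_mean_matrix = matrix(1, 2, 2),
                             weight_sd_matrix = matrix(0.1, 2, 2)),
               "not symmetric")
  expect_error(cohort_config(5, n_nodes = 8, k_planted = 2,
                             edge_rate_matrix = matrix(0.5, 2, 2),
                             weight_mean_matrix = matrix(1, 2, 2),
                             weight_sd_matrix = matrix(0, 2, 2)),
               "SDs")

  cfg <- default_cohort_config(n_subjects = 4, n_nodes = 20, k_planted = 3,
                               rng_seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$table, c2$table)
  expect_identical(lapply(c1$subjects, function(s) s$connectome$weights),
                   lapply(c2$subjects, function(s) s$connectome$weights))
  expect_equal(nrow(c1$table), 4)
  expect_true(all(c1$table$age >= 6 & c1$table$age <= 85))
})

test_that("generated networks are symmetric, hollow and non-negative", {
  cfg <- default_cohort_config(n_subjects = 3, n_nodes = 30, k_planted = 3,
                               rng_seed = 4)
  ch <- generate_cohort(cfg)
  for (s in ch$subjects) {
    W <- s$connectome$weights
    expect_equal(W, t(W))
    expect_equal(diag(W), rep(0, 30))
    expect_true(all(W >= 0))
  }
})

test_that("planted quadratic trend is recoverable; zero trend is flat", {
  k <- 2
  base <- function(trend, n_subj, seed) {
    spec <- make_trend_spec(k)
    spec <- set_trend(spec, k, 1, 1, trend)
    cohort_config(n_subj, n_nodes = 20, k_planted = k,
                  edge_rate_matrix = matrix(c(2, 0.3, 0.3, 2), 2),
                  weight_mean_matrix = matrix(c(0.5, 0.1, 0.1, 0.5), 2),
                  weight_sd_matrix = matrix(0.05, 2, 2),
                  trend_spec = spec, rng_seed = seed)
  }
  # quadratic planted at peak 40: OLS quadratic on true block strength
  # recovers the peak age within +/- 5 years at n = 200
  ch <- generate_cohort(base(trend_quadratic(40, 0.2), 200, 11))
  y <- vapply(ch$subjects, function(s) {
    block_summary(s$connectome, s$true_partition, "total")$values[1, 1]
  }, numeric(1))
  f <- lm(y ~ age + I(age^2), data.frame(y = y, age = ch$table$age))
  peak <- -coef(f)[2] / (2 * coef(f)[3])
  expect_lt(abs(peak - 40), 5)

  # amplitude 0: regression slope CI covers 0 at n = 500
  ch0 <- generate_cohort(base(trend_none(), 500, 12))
  y0 <- vapply(ch0$subjects, function(s) {
    block_summary(s$connectome, s$true_partition, "total")$values[1, 1]
  }, numeric(1))
  ci <- confint(lm(y0 ~ age, data.frame(y0 = y0, age = ch0$table$age)))["age", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("cohort files are written 1-based and complete", {
  cfg <- default_cohort_config(n_subjects = 3, n_nodes = 12, k_planted = 2,
                               rng_seed = 5)
  ch <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_true(file.exists(file.path(dir, "subject_001.txt")))
  expect_true(file.exists(file.path(dir, "nodes.tsv")))
  tab <- read.csv(file.path(dir, "subjects.csv"))
  expect_equal(tab$id, 1:3)
  truth <- read.table(file.path(dir, "truth.tsv"), header = TRUE)
  expect_equal(truth$node, 1:12)
  expect_equal(truth$planted_block, ch$truth$labels)
  A <- read_connectome(file.path(dir, "subject_002.txt"))
  expect_equal(A$weights, ch$subjects[[2]]$connectome$weights)
})
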