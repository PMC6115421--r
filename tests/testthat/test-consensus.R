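test_that("stage-1 search maximises over its trial seed stream", {
  cl <- make_cliques(c(4, 4), within = 1, between = 0.05)
  expect_error(stage1_fit(cl$W, 2, n_trials = 0), "n_trials")

  # n_trials = 1 is exactly one fit at the first derived seed
  s1 <- stage1_fit(cl$W, 2, n_trials = 1, seed = 42)
  set.seed(42)
  first_seed <- sample.int(.Machine$integer.max - 1L, 1)
  expect_identical(s1$log_evidence,
                   fit_wsbm(cl$W, 2, seed = first_seed)$log_evidence)

  # a superset of trials can only improve the best bound (shared prefix)
  b3 <- stage1_fit(cl$W, 2, n_trials = 3, seed = 7)
  b8 <- stage1_fit(cl$W, 2, n_trials = 8, seed = 7)
  expect_gte(b8$log_evidence, b3$log_evidence)

  expect_equal(nmi(stage1_fit(cl$W, 2, n_trials = 5, seed = 1)$map_partition,
                   partition(cl$labels)), 1)
})

test_that("stage-2 concentration ladder behaves at its limits", {
  cl <- make_cliques(c(5, 5), within = 1, between = 0.05)
  truth <- partition(cl$labels)
  expect_error(stage2_refine(cl$W, 2, truth, ladder = numeric(0)), "empty")

  # enormous concentration: the seed partition dominates
  r <- stage2_refine(cl$W, 2, truth, ladder = 1e6, n_trials = 2, seed = 1)
  expect_equal(nmi(r$map_partition, truth), 1)

  # refinement on separable data does not lose ground on the bound
  s1 <- stage1_fit(cl$W, 2, n_trials = 5, seed = 3)
  r2 <- stage2_refine(cl$W, 2, s1$map_partition, ladder = c(1, 2),
                      n_trials = 5, seed = 4)
  expect_gte(r2$log_evidence, s1$log_evidence - 1e-6)
})

test_that("k selection recovers a planted k = 3 and handles edge cases", {
  cfg <- default_cohort_config(n_subjects = 1, n_nodes = 42, k_planted = 3,
                               rng_seed = 13)
  A <- sample_subject(cfg, age = 30, seed = 5)$connectome
  sel <- select_k(A, k_range = 2:5, n_fits = 6, seed = 2)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$table), 4)

  one <- select_k(A, k_range = 3, n_fits = 2, seed = 1)
  expect_equal(one$k, 3)
  expect_error(select_k(A, k_range = integer(0)), "empty")

  # mean over a single fit equals that fit's evidence
  single <- select_k(A, k_range = 3, n_fits = 1, seed = 9)
  set.seed(9); ks <- sample.int(.Machine$integer.max - 1L, 1)
  set.seed(ks); fs <- sample.int(.Machine$integer.max - 1L, 1)
  expect_identical(single$table$mean_log_evidence,
                   fit_wsbm(A, 3, seed = fs)$log_evidence)
})

test_that("the consensus loop converges, is deterministic and row-stochastic", {
  cl <- make_cliques(c(6, 6), within = 1, between = 0.02)
  res <- consensus_loop(cl$W, 2, n_fits = 8, seed = 3)
  expect_true(res$converged)
  expect_lte(res$n_outer_iterations, 3)
  expect_equal(nmi(res$partition, partition(cl$labels)), 1)
  expect_equal(rowSums(res$frequency_prior), rep(1, 12))
  # huge separation: frequency rows one-hot
  expect_true(all(apply(res$frequency_prior, 1, max) == 1))

  res2 <- consensus_loop(cl$W, 2, n_fits = 8, seed = 3)
  expect_identical(res$partition$labels, res2$partition$labels)
  expect_identical(res$frequency_prior, res2$frequency_prior)
})

test_that("bootstrap-resampled frequency priors give stable consensus", {
  cfg <- default_cohort_config(n_subjects = 1, n_nodes = 40, k_planted = 4,
                               rng_seed = 19)
  A <- sample_subject(cfg, age = 30, seed = 3)$connectome
  ref <- consensus_loop(A, 4, n_fits = 10, seed = 5)
  set.seed(99)
  nmis <- replicate(5, {
    cols <- sample(ncol(ref$aligned_labels), replace = TRUE)
    M <- ref$aligned_labels[, cols, drop = FALSE]
    freq <- t(apply(M, 1, tabulate, nbins = 4)) / ncol(M)
    boot <- consensus_loop(A, 4, n_fits = 10, seed = 6,
                           init_prior = frequency_prior(freq))
    nmi(boot$partition, ref$partition)
  })
  expect_gte(mean(nmis), 0.8)
})

test_that("subject fits follow the consensus prior contract", {
  cl <- make_cliques(c(5, 5), within = 1, between = 0.05)
  truth <- partition(cl$labels)
  expect_error(fit_subject(cl$W[1:8, 1:8], truth), "node count")

  # infinite concentration returns the consensus partition itself
  p <- fit_subject(cl$W, truth, concentration = 1e9, n_fits = 1, seed = 1)
  expect_equal(nmi(p, truth), 1)

  # n_fits = 1 equals the single underlying fit
  p1 <- fit_subject(cl$W, truth, concentration = 3, n_fits = 1, seed = 8)
  set.seed(8); s <- sample.int(.Machine$integer.max - 1L, 1)
  f <- fit_wsbm(cl$W, 2, prior = concentrated_prior(truth, 2, 3), seed = s)
  expect_identical(p1$labels, f$map_partition$labels)

  # subjects sampled from the consensus model are recovered on average
  cfg <- default_cohort_config(n_subjects = 5, n_nodes = 36, k_planted = 3,
                               rng_seed = 23)
  ch <- generate_cohort(cfg)
  nmis <- vapply(ch$subjects, function(s) {
    nmi(fit_subject(s$connectome, ch$truth, n_fits = 3, seed = 4), ch$truth)
  }, numeric(1))
  expect_gte(mean(nmis), 0.8)
})
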