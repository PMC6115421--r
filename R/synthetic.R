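# Synthetic bilateral connectome cohorts with planted WSBM structure.
#
# The generator emulates the stated world of the lifespan connectome study:
# 114-node bilateral networks, ~25-30% binary density, k ~ 10 planted blocks
# with mixed (assortative / disassortative / core-periphery) affinity
# patterns, Poisson edge existence, Normal edge weights, and age-modulated
# block-weight trends over ages 6-85 with sex and motion nuisance effects.

#' Age-trend specifications for block-pair weights
#'
#' Each block pair of a synthetic cohort carries one trend describing how its
#' mean edge weight varies with age: none, linear (slope per year, centred on
#' the midpoint of the age range), inverted-U quadratic (amplitude at
#' `peak_age`, decaying to zero at the range edges), or a Poisson curve
#' `beta1 * age * exp(-beta2 * age)`.
#'
#' @param slope weight units per year
#' @param peak_age years at which the quadratic trend peaks
#' @param amplitude weight-units height of the quadratic at its peak
#' @param beta1,beta2 Poisson-curve coefficients
#' @return a trend spec list with a `type` field
#' @export
trend_none <- function() list(type = "none")

#' @rdname trend_none
#' @export
trend_linear <- function(slope) list(type = "linear", slope = slope)

#' @rdname trend_none
#' @export
trend_quadratic <- function(peak_age, amplitude) {
  list(type = "quadratic", peak_age = peak_age, amplitude = amplitude)
}

#' @rdname trend_none
#' @export
trend_poisson_curve <- function(beta1, beta2) {
  list(type = "poisson_curve", beta1 = beta1, beta2 = beta2)
}

trend_value <- function(spec, age, age_range) {
  switch(spec$type,
    none = 0,
    linear = spec$slope * (age - mean(age_range)),
    quadratic = {
      half <- (age_range[2] - age_range[1]) / 2
      spec$amplitude * (1 - ((age - spec$peak_age) / half)^2)
    },
    poisson_curve = spec$beta1 * age * exp(-spec$beta2 * age),
    stop("unknown trend type: ", spec$type))
}

#' Uniform trend specification for all block pairs
#'
#' @param k block count
#' @param default trend applied to every pair (see [trend_none()])
#' @return list of length `(k^2-k)/2 + k` in [block_pairs()] order
#' @export
make_trend_spec <- function(k, default = trend_none()) {
  replicate(nrow(block_pairs(k)), default, simplify = FALSE)
}

#' Set the trend of one block pair
#' @param spec trend spec list from [make_trend_spec()]
#' @param k block count
#' @param i,j block pair (order irrelevant)
#' @param trend trend object
#' @return updated spec list
#' @export
set_trend <- function(spec, k, i, j, trend) {
  bp <- block_pairs(k)
  idx <- which(bp$i == min(i, j) & bp$j == max(i, j))
  stopifnot(length(idx) == 1)
  spec[[idx]] <- trend
  spec
}

#' Synthetic cohort configuration
#'
#' Bundles all parameters of the synthetic connectome generator. Matrices are
#' k x k and symmetric; `edge_rate_matrix` holds Poisson edge-existence rates
#' (presence probability `1 - exp(-rate)`), `weight_mean_matrix` baseline
#' streamline-density-like weight means, `weight_sd_matrix` weight standard
#' deviations (all > 0).
#'
#' @param n_subjects cohort size
#' @param n_nodes even node count (half per hemisphere)
#' @param k_planted planted block count
#' @param age_range `c(min, max)` in years
#' @param edge_rate_matrix,weight_mean_matrix,weight_sd_matrix k x k symmetric
#' @param trend_spec per-block-pair trend list (see [make_trend_spec()])
#' @param sex_effect additive weight offset applied when `sex == 1`
#' @param motion_noise_sd weight decrement per unit of subject motion
#' @param weight_floor positive clip floor for sampled weights
#' @param block_sizes optional per-block homotopic-pair counts (sum `n/2`)
#' @param rng_seed integer seed
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_subjects, n_nodes = 114L, k_planted = 10L,
                          age_range = c(6, 85),
                          edge_rate_matrix, weight_mean_matrix,
                          weight_sd_matrix,
                          trend_spec = make_trend_spec(k_planted),
                          sex_effect = 0, motion_noise_sd = 0,
                          weight_floor = 1e-6, block_sizes = NULL,
                          rng_seed = 1L) {
  if (n_subjects < 1) stop("invalid config: n_subjects must be >= 1")
  if (n_nodes %% 2 != 0) stop("invalid config: n_nodes must be even")
  if (k_planted > n_nodes) stop("invalid config: more blocks than nodes")
  k <- k_planted
  chk <- function(M, nm) {
    M <- as.matrix(M)
    if (!all(dim(M) == c(k, k))) stop("invalid config: ", nm, " must be k x k")
    if (max(abs(M - t(M))) > .SYM_TOL) stop("invalid config: ", nm, " not symmetric")
    M
  }
  edge_rate_matrix <- chk(edge_rate_matrix, "edge_rate_matrix")
  weight_mean_matrix <- chk(weight_mean_matrix, "weight_mean_matrix")
  weight_sd_matrix <- chk(weight_sd_matrix, "weight_sd_matrix")
  if (any(edge_rate_matrix < 0)) stop("invalid config: negative edge rates")
  if (any(weight_sd_matrix <= 0)) stop("invalid config: weight SDs must be > 0")
  if (length(trend_spec) != nrow(block_pairs(k))) {
    stop("invalid config: trend_spec must cover all (k^2-k)/2 + k block pairs")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
    k_planted = as.integer(k), age_range = age_range,
    edge_rate_matrix = edge_rate_matrix,
    weight_mean_matrix = weight_mean_matrix,
    weight_sd_matrix = weight_sd_matrix,
    trend_spec = trend_spec, sex_effect = sex_effect,
    motion_noise_sd = motion_noise_sd, weight_floor = weight_floor,
    block_sizes = block_sizes, rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

#' Default mixed-topology cohort configuration
#'
#' A stated-world default: k = 10 blocks on 114 nodes with mostly assortative
#' blocks, one disassortative block (weakly connected within, strongly to two
#' partners) and one core-periphery motif, chosen so the overall binary
#' density lands near 25-30%. Within/between weight-mean separation is about
#' 3 pooled SD, making planted recovery nontrivial but feasible.
#'
#' @inheritParams cohort_config
#' @param ... overrides passed to [cohort_config()]
#' @return a `cohort_config`
#' @export
default_cohort_config <- function(n_subjects = 100L, n_nodes = 114L,
                                  k_planted = 10L, rng_seed = 1L, ...) {
  k <- k_planted
  # presence probabilities: dense within, sparse between -> overall ~25-30%
  p <- matrix(0.22, k, k)
  diag(p) <- 0.65
  mu <- matrix(0.04, k, k)
  diag(mu) <- 0.22
  if (k >= 6) {
    # disassortative block: weak inside, strong to blocks k-1 and k-2
    d <- k - 3
    p[d, d] <- 0.18; mu[d, d] <- 0.05
    p[d, k - 1] <- p[k - 1, d] <- 0.6; mu[d, k - 1] <- mu[k - 1, d] <- 0.2
    p[d, k - 2] <- p[k - 2, d] <- 0.55; mu[d, k - 2] <- mu[k - 2, d] <- 0.18
    # core-periphery: block 1 core, block 2 periphery attached to the core
    p[1, 2] <- p[2, 1] <- 0.55; mu[1, 2] <- mu[2, 1] <- 0.16
    p[2, 2] <- 0.12; mu[2, 2] <- 0.05
  }
  rate <- -log(1 - p)
  sdm <- matrix(0.05, k, k)
  sizes <- if (k == 10 && n_nodes == 114) c(3, 4, 5, 5, 6, 6, 6, 7, 7, 8) else NULL
  cohort_config(n_subjects = n_subjects, n_nodes = n_nodes, k_planted = k,
                edge_rate_matrix = rate, weight_mean_matrix = mu,
                weight_sd_matrix = sdm, block_sizes = sizes,
                rng_seed = rng_seed, ...)
}

#' Planted bilateral partition
#'
#' Nodes `1..n/2` form the left hemisphere and `n/2+1..n` the right; node `i`
#' and `i + n/2` are homotopic partners. In bilateral mode partners share a
#' block, so every block holds nodes from both hemispheres.
#'
#' @param n_nodes even node count
#' @param k_planted block count (at most `n_nodes/2` in bilateral mode)
#' @param bilateral mirror blocks across hemispheres (default TRUE)
#' @param sizes optional per-block homotopic-pair counts summing to
#'   `n_nodes/2` (node counts, summing to `n_nodes`, when `bilateral = FALSE`)
#' @return a `partition`
#' @export
make_planted_partition <- function(n_nodes, k_planted, bilateral = TRUE,
                                   sizes = NULL) {
  if (k_planted > n_nodes) stop("invalid config: k_planted exceeds n_nodes")
  if (bilateral) {
    if (n_nodes %% 2 != 0) stop("invalid config: bilateral needs even n_nodes")
    half <- n_nodes / 2
    if (k_planted > half) stop("invalid config: k_planted exceeds n_nodes/2")
    if (is.null(sizes)) {
      sizes <- rep(half %/% k_planted, k_planted)
      extra <- half - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    }
    stopifnot(sum(sizes) == half, all(sizes >= 1))
    pair_block <- rep(seq_len(k_planted), times = sizes)
    partition(c(pair_block, pair_block), k = k_planted)
  } else {
    if (is.null(sizes)) {
      sizes <- rep(n_nodes %/% k_planted, k_planted)
      extra <- n_nodes - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    }
    stopifnot(sum(sizes) == n_nodes)
    partition(rep(seq_len(k_planted), times = sizes), k = k_planted)
  }
}

#' Mirrored jittered node coordinates
#'
#' Left-hemisphere nodes get x < 0, right-hemisphere x > 0; homotopic
#' partners are mirror images. Positions sit on a jittered 3-D grid inside a
#' brain-sized box (mm).
#'
#' @param n_nodes even node count
#' @param seed RNG seed for the jitter
#' @return node metadata data.frame (id, hemisphere, x, y, z, name)
#' @export
make_node_coords <- function(n_nodes, seed = 1L) {
  stopifnot(n_nodes %% 2 == 0)
  half <- n_nodes / 2
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  g <- ceiling(half^(1 / 3))
  grid <- expand.grid(gx = seq_len(g), gy = seq_len(g), gz = seq_len(g))[seq_len(half), ]
  x <- -15 - (grid$gx - 1) / max(1, g - 1) * 50 + runif(half, -3, 3)   # [-68, -12]
  y <- -55 + (grid$gy - 1) / max(1, g - 1) * 110 + runif(half, -3, 3)
  z <- -25 + (grid$gz - 1) / max(1, g - 1) * 70 + runif(half, -3, 3)
  data.frame(
    id = seq_len(n_nodes),
    hemisphere = rep(c("L", "R"), each = half),
    x = c(x, -x), y = c(y, y), z = c(z, z),
    name = c(sprintf("L_%02d", seq_len(half)), sprintf("R_%02d", seq_len(half))),
    stringsAsFactors = FALSE)
}

# sample one symmetric network given node-level label vector and k x k
# block parameters; mean_shift is added to every pair mean (age/sex/motion)
.sample_block_network <- function(rate_k, mean_k, sd_k, labels, floor,
                                  mean_shift_k = NULL) {
  n <- length(labels)
  W <- matrix(0, n, n)
  iu <- which(upper.tri(W))
  ri <- row(W)[iu]; ci <- col(W)[iu]
  bi <- labels[ri]; bj <- labels[ci]
  rates <- rate_k[cbind(bi, bj)]
  present <- rpois(length(iu), rates) >= 1
  if (any(present)) {
    mu <- mean_k[cbind(bi, bj)][present]
    if (!is.null(mean_shift_k)) mu <- mu + mean_shift_k[cbind(bi, bj)][present]
    w <- rnorm(sum(present), mu, sd_k[cbind(bi, bj)][present])
    W[iu[present]] <- pmax(w, floor)
  }
  W + t(W)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Sample one synthetic subject
#'
#' Edge presence is Poisson-with-truncation (count >= 1 means the edge
#' exists); present edges draw a Normal weight with mean
#' `baseline + trend(age) + sex_effect * sex - motion_noise_sd * motion`,
#' clipped at the configured positive floor.
#'
#' @param config a `cohort_config`
#' @param age subject age in years
#' @param sex 0/1 indicator
#' @param motion non-negative motion index
#' @param seed RNG seed
#' @param nodes optional precomputed node metadata
#' @return list with `connectome`, `true_partition`, `age`, `sex`, `motion`,
#'   `total_strength`
#' @export
sample_subject <- function(config, age, sex = 0L, motion = 0, seed = 1L,
                           nodes = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  k <- config$k_planted
  truth <- make_planted_partition(config$n_nodes, k, bilateral = TRUE,
                                  sizes = config$block_sizes)
  if (is.null(nodes)) nodes <- make_node_coords(config$n_nodes, seed = config$rng_seed)
  shift <- roll_blocks(
    vapply(config$trend_spec, trend_value, numeric(1),
           age = age, age_range = config$age_range), k)
  shift <- shift + config$sex_effect * sex - config$motion_noise_sd * motion
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  W <- .sample_block_network(config$edge_rate_matrix,
                             config$weight_mean_matrix,
                             config$weight_sd_matrix,
                             truth$labels, config$weight_floor,
                             mean_shift_k = shift)
  A <- connectome(W, nodes = nodes)
  list(connectome = A, true_partition = truth, age = age,
       sex = as.integer(sex), motion = motion,
       total_strength = total_strength(A))
}

#' Generate a synthetic cohort
#'
#' Ages are uniform over the configured range; sex is balanced Bernoulli(0.5)
#' and motion is folded-Normal. The whole cohort is reproducible from
#' `config$rng_seed`.
#'
#' @param config a `cohort_config`
#' @return list with `subjects` (list of [sample_subject()] results),
#'   `table` (data.frame: id, age, sex, motion, total_strength) and `truth`
#'   (the planted `partition`)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(config$rng_seed)
  ages <- runif(n, config$age_range[1], config$age_range[2])
  sexes <- rbinom(n, 1, 0.5)
  motions <- abs(rnorm(n))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  nodes <- make_node_coords(config$n_nodes, seed = config$rng_seed)
  subjects <- lapply(seq_len(n), function(i) {
    sample_subject(config, ages[i], sexes[i], motions[i], seed = seeds[i],
                   nodes = nodes)
  })
  tab <- data.frame(
    id = seq_len(n), age = ages, sex = sexes, motion = motions,
    total_strength = vapply(subjects, `[[`, numeric(1), "total_strength"))
  list(subjects = subjects, table = tab,
       truth = subjects[[1]]$true_partition)
}

#' Write a cohort to a directory
#'
#' Emits one dense matrix file per subject (`subject_###.txt`), `nodes.tsv`,
#' `subjects.csv` and `truth.tsv` (planted blocks). All node ids 1-based.
#'
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$subjects)) {
    write_connectome(cohort$subjects[[i]]$connectome,
                     file.path(dir, sprintf("subject_%03d.txt", i)))
  }
  write_nodes(cohort$subjects[[1]]$connectome$nodes, file.path(dir, "nodes.tsv"))
  write.csv(cohort$table, file.path(dir, "subjects.csv"), row.names = FALSE)
  write.table(data.frame(node = seq_along(cohort$truth$labels),
                         planted_block = cohort$truth$labels),
              file.path(dir, "truth.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(dir)
}
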