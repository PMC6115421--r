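# Independent brute-force oracles used across the suite. These deliberately
# use loop-based, direct-definition computations and never call the package
# code paths they check.

perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

entropy_oracle <- function(labels) {
  f <- table(labels) / length(labels)
  -sum(f * log(f))
}

mi_oracle <- function(a, b) {
  n <- length(a)
  s <- 0
  for (x in unique(a)) for (y in unique(b)) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) s <- s + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  s
}

vi_oracle <- function(a, b) entropy_oracle(a) + entropy_oracle(b) - 2 * mi_oracle(a, b)

nmi_oracle <- function(a, b) {
  d <- (entropy_oracle(a) + entropy_oracle(b)) / 2
  if (d == 0) 1 else mi_oracle(a, b) / d
}

brute_assignment_cost <- function(cost) {
  k <- nrow(cost)
  best <- Inf
  for (p in perms(k)) {
    v <- sum(cost[cbind(seq_len(k), unlist(p))])
    if (v < best) best <- v
  }
  best
}

q_oracle <- function(W, labels, gamma = 1) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  s <- colSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] == labels[j]) q <- q + W[i, j] - gamma * s[i] * s[j] / m2
  }
  q / m2
}

best_bipartition_q <- function(W, gamma = 1) {
  n <- nrow(W)
  best <- q_oracle(W, rep(1, n), gamma)
  for (mask in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(mask))[1:n] + 1L
    best <- max(best, q_oracle(W, lab, gamma))
  }
  best
}

ks_oracle <- function(x, y) {
  g <- sort(unique(c(x, y)))
  d <- 0
  for (t in g) d <- max(d, abs(sum(x <= t) / length(x) - sum(y <= t) / length(y)))
  d
}

clustering_oracle <- function(X) {
  n <- nrow(X)
  sapply(seq_len(n), function(i) {
    nb <- which(X[i, ] > 0)
    d <- length(nb)
    if (d < 2) return(0)
    tri <- 0
    for (a in nb) for (b in nb) if (a < b && X[a, b] > 0) tri <- tri + 1
    2 * tri / (d * (d - 1))
  })
}

betweenness_oracle <- function(X) {
  n <- nrow(X)
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[X > 0] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  nsp <- matrix(0, n, n)  # number of shortest paths
  for (s in 1:n) {
    ord <- order(D[s, ])
    nsp[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(X[, v] > 0 & D[s, ] == D[s, v] - 1)
      nsp[s, v] <- sum(nsp[s, pred])
    }
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    for (v in 1:n) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        btw[v] <- btw[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
      }
    }
  }
  btw
}

icc31_aov_oracle <- function(M) {
  d <- data.frame(y = as.numeric(M),
                  target = factor(rep(seq_len(nrow(M)), ncol(M))),
                  rater = factor(rep(seq_len(ncol(M)), each = nrow(M))))
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][["Mean Sq"]]
  bms <- ms[1]; ems <- ms[3]
  (bms - ems) / (bms + (ncol(M) - 1) * ems)
}

make_cliques <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), times = sizes)
  W <- matrix(between, n, n)
  for (b in seq_along(sizes)) {
    idx <- which(lab == b)
    W[idx, idx] <- within
  }
  diag(W) <- 0
  list(W = W, labels = lab)
}

rand_partition <- function(n, k) {
  labs <- sample.int(k, n, replace = TRUE)
  # guarantee every label 1..max appears contiguously renumbered
  partition(as.integer(factor(labs)))
}

rand_coords <- function(n) cbind(runif(n, -50, 50), runif(n, -50, 50),
                                 runif(n, -30, 30))

rand_connectome <- function(n, density = 0.4, coords = TRUE) {
  W <- matrix(0, n, n)
  iu <- which(upper.tri(W))
  on <- runif(length(iu)) < density
  W[iu[on]] <- runif(sum(on), 0.05, 1)
  W <- W + t(W)
  nodes <- NULL
  if (coords) {
    xyz <- rand_coords(n)
    nodes <- data.frame(id = 1:n,
                        hemisphere = rep(c("L", "R"), length.out = n),
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        name = paste0("n", 1:n))
  }
  connectome(W, nodes = nodes)
}
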