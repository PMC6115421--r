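# Partition comparison: variation of information, normalized mutual
# information, VI centroids, and Hungarian (Munkres) label alignment.

.part_entropy_terms <- function(p, q) {
  lp <- part_labels(p); lq <- part_labels(q)
  if (length(lp) != length(lq)) stop("partitions have different node counts")
  n <- length(lp)
  tab <- table(lp, lq) / n
  pr <- rowSums(tab); pc <- colSums(tab)
  H <- function(x) { x <- x[x > 0]; -sum(x * log(x)) }
  nz <- tab > 0
  I <- sum(tab[nz] * log(tab[nz] / outer(pr, pc)[nz]))
  list(Hp = H(pr), Hq = H(pc), I = I)
}

#' Variation of information between two partitions
#'
#' `VI = H(p) + H(q) - 2 I(p; q)` in nats. A metric on partitions: 0 iff the
#' partitions are identical up to relabeling.
#'
#' @param p,q partitions (or label vectors) over the same nodes
#' @return non-negative scalar (nats)
#' @export
vi_distance <- function(p, q) {
  e <- .part_entropy_terms(p, q)
  max(e$Hp + e$Hq - 2 * e$I, 0)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalised by the arithmetic mean of the two label
#' entropies; in `[0, 1]`, 1 for identical partitions. Two trivial
#' single-block partitions (zero entropy on both sides) return 1.
#'
#' @inheritParams vi_distance
#' @return scalar in `[0, 1]`
#' @export
nmi <- function(p, q) {
  e <- .part_entropy_terms(p, q)
  denom <- (e$Hp + e$Hq) / 2
  if (denom == 0) return(1)
  min(max(e$I / denom, 0), 1)
}

#' VI-centroid of a list of partitions
#'
#' Index of the partition with minimum summed VI distance to all others
#' (ties broken by the lowest index).
#'
#' @param partitions non-empty list of partitions
#' @return integer index into `partitions`
#' @export
find_centroid <- function(partitions) {
  if (length(partitions) < 1) stop("empty partition list")
  m <- length(partitions)
  if (m == 1) return(1L)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      D[i, j] <- D[j, i] <- vi_distance(partitions[[i]], partitions[[j]])
    }
  }
  which.min(rowSums(D))
}

#' Solve the linear assignment problem (Hungarian / Munkres)
#'
#' Minimum-cost perfect matching on a square cost matrix via the O(n^3)
#' shortest augmenting path algorithm with potentials.
#'
#' @param cost square numeric cost matrix
#' @return integer vector `a` with `a[i]` the column assigned to row `i`
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  # columns indexed 1..n+1 internally; index 1 is a virtual dummy column
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0 + 1] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j] + 1] <- u[p[j] + 1] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  for (j in 2:(n + 1)) out[p[j]] <- j - 1L
  out
}

#' Align partitions to a reference by Munkres label matching
#'
#' Relabels each partition so that total label overlap with the reference is
#' maximised (Hungarian algorithm on negated contingency counts). Node
#' memberships are unchanged as sets; only labels move. Partitions with
#' fewer blocks than the common `k` are padded with empty blocks.
#'
#' @param partitions list of partitions (or a single partition)
#' @param reference reference `partition`
#' @return list of aligned `partition`s (same length and order)
#' @export
align_partitions <- function(partitions, reference) {
  single <- inherits(partitions, "partition")
  if (single) partitions <- list(partitions)
  k <- max(part_k(reference), vapply(partitions, part_k, integer(1)))
  ref <- part_labels(reference)
  out <- lapply(partitions, function(p) {
    lab <- part_labels(p)
    C <- matrix(0, k, k)  # rows: candidate labels, cols: reference labels
    tab <- table(factor(lab, levels = 1:k), factor(ref, levels = 1:k))
    C[] <- as.numeric(tab)
    a <- solve_assignment(-C)      # a[c]: new label for old label c
    partition(a[lab], k = k)
  })
  if (single) out[[1]] else out
}

#' Total label overlap between two partitions
#' @inheritParams vi_distance
#' @return count of nodes with equal labels
#' @export
label_overlap <- function(p, q) {
  sum(part_labels(p) == part_labels(q))
}
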