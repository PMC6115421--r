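# Group-representative connectome by distance-binned constrained averaging:
# match the subject-average edge density while preserving the edge-length
# distribution (Euclidean inter-node distance standing in for streamline
# length).

#' Age-window subset of a cohort
#'
#' Config-style filter on the subject table (the young-adult window used to
#' build representative matrices is ages 25-35).
#'
#' @param cohort result of [generate_cohort()]
#' @param age_min,age_max inclusive age window in years
#' @return a cohort list restricted to the window
#' @export
subset_cohort_ages <- function(cohort, age_min = 25, age_max = 35) {
  keep <- which(cohort$table$age >= age_min & cohort$table$age <= age_max)
  list(subjects = cohort$subjects[keep],
       table = cohort$table[keep, , drop = FALSE],
       truth = cohort$truth)
}

#' Build a distance-binned group-representative connectome
#'
#' Node pairs are binned by inter-node Euclidean distance into `n_bins`
#' equal-width bins. Within each bin, pairs are ranked by cross-subject
#' occurrence frequency (ties by higher mean nonzero weight, then by lower
#' node-index pair) and retained until the bin holds the rounded (nearest,
#' ties to even) average per-subject edge count for that bin. Retained
#' edges carry the mean of the nonzero subject weights, so the overall
#' binary density matches the subject average within rounding.
#'
#' @param cohort list of `connectome`s with identical node sets (>= 2), the
#'   first of which must carry node coordinates
#' @param n_bins number of distance bins (default 10)
#' @return a `connectome`; attribute `provenance` records bin edges and
#'   per-bin target/retained counts
#' @export
build_representative <- function(cohort, n_bins = 10L) {
  if (length(cohort) < 2) stop("need at least 2 subjects")
  if (n_bins < 1) stop("n_bins must be >= 1")
  n <- n_nodes(cohort[[1]])
  stopifnot(all(vapply(cohort, n_nodes, integer(1)) == n))
  coords <- conn_coords(cohort[[1]])
  D <- as.matrix(dist(coords))
  iu <- which(upper.tri(D))
  d <- D[iu]
  edges <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d, edges, rightmost.closed = TRUE), 1L), n_bins)

  ns <- length(cohort)
  Ws <- lapply(cohort, conn_weights)
  occ <- Reduce(`+`, lapply(Ws, function(W) (W[iu] > 0) * 1))
  wsum <- Reduce(`+`, lapply(Ws, function(W) W[iu]))
  meanw <- ifelse(occ > 0, wsum / occ, 0)

  keep <- logical(length(iu))
  prov <- data.frame(bin = seq_len(n_bins), lo = edges[-length(edges)],
                     hi = edges[-1], target = 0L, retained = 0L)
  for (b in seq_len(n_bins)) {
    idx <- which(bin == b)
    if (length(idx) == 0) next
    target <- as.integer(round(sum(occ[idx]) / ns))
    avail <- idx[occ[idx] > 0]
    if (target > 0 && length(avail) > 0) {
      ord <- avail[order(-occ[avail], -meanw[avail], avail)]
      sel <- ord[seq_len(min(target, length(ord)))]
      keep[sel] <- TRUE
      prov$retained[b] <- length(sel)
    }
    prov$target[b] <- target
  }
  W <- matrix(0, n, n)
  W[iu[keep]] <- meanw[keep]
  W <- W + t(W)
  out <- connectome(W, nodes = if (inherits(cohort[[1]], "connectome"))
    cohort[[1]]$nodes else NULL)
  attr(out, "provenance") <- prov
  out
}
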