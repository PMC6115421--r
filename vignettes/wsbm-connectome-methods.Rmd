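---
title: "Methods: weighted stochastic block models for structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted stochastic block models for structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

A structural connectome is summarised here as a symmetric, non-negative
weighted adjacency matrix with zero diagonal; weights are
streamline-density-like quantities attached to cortical parcels that carry
hemisphere labels and 3-D coordinates in mm. The weighted stochastic block
model (WSBM) assigns every node to one of `k` blocks and treats all nodes in
a block as stochastically equivalent. Per unordered block pair `(r, s)`:

* edge existence is drawn from a Poisson distribution with rate
  `theta_rs`, truncated so that a count of one or more means the edge
  exists;
* existing edges draw a Normal weight with mean `mu_rs` and variance
  `sigma2_rs`.

Missing edges contribute only to the existence component: weights are
modelled conditionally on existence. The two likelihood components are
combined with a mixing weight `alpha` (default 0.5, exposed in
`fit_wsbm()`). There is no field consensus on how to weight the two
components, and both parameter families carry real signal in structural
networks, so equal weighting is the neutral default.

Unlike modularity maximization, which only rewards dense within-community
connectivity, this parameterisation can express assortative, disassortative,
core-periphery and mixed mesoscale organisation — the motivation for using
it on brain networks.

## Inference

`fit_wsbm()` runs coordinate-ascent variational Bayes with conjugate
priors: Gamma(1, 1) on existence rates and Normal-Gamma on weight
mean/precision, centred on the sample mean and variance of the nonzero
weights (kappa0 = a0 = 1). Node assignments have a categorical prior given
by a configurable n x k concentration matrix. Responsibility rows are
updated sequentially (node by node), which keeps the evidence lower bound
non-decreasing; the implementation aborts if the bound ever falls by more
than 1e-6 nats, so every fit in the test suite doubles as a monotonicity
assertion. Iteration stops when the absolute bound change drops below 1e-4
nats or after 200 sweeps. Hard assignments are row-wise argmax with ties to
the lowest block index.

Two numerical choices deserve explanation:

* **Initialisation.** Trials under a uniform prior start from a randomized
  spectral embedding: the top-k adjacency eigenvectors (scaled by the root
  of their eigenvalues) are clustered by k-means from random starts, and
  the resulting hard labels seed the first M-step. A plain random start
  collapses the ascent into the one-block local optimum on most runs —
  coordinate ascent cannot split two blocks whose parameters initialise as
  near-identical mixtures. The embedding varies across seeds through the
  k-means starts, so repeated trials still explore distinct solutions, which
  the consensus machinery requires. Trials under a biased (concentrated or
  frequency) prior instead start from a random draw of that prior.
* **Rate scale of reported parameters.** The variational likelihood
  evaluates the Poisson density on the binary existence indicator, so the
  Gamma posterior mean estimates the *probability* that an edge exists.
  Reported generative parameters convert this to the truncated-Poisson
  scale, `edge_rate = -log(1 - p)`, the inverse of
  `P(count >= 1) = 1 - exp(-rate)`. Without the conversion a fitted model
  generates networks systematically sparser than the data it was fitted to.
  The same inverse link is used when estimating parameters under a fixed
  modular partition (`modular_as_generative()`).

## Fitting workflow

The full pipeline mirrors the staged strategy used for the lifespan
analysis: `stage1_fit()` keeps the best of many (default 250)
uniform-prior trials; `stage2_refine()` ramps a concentrated prior over the
ladder `1 + c` with `c = 1.0, 1.5, ..., 6.0` (the "100% higher, then
150%...600%" ramp); `select_k()` compares candidate block counts (default
6..11) by the mean variational log-evidence of repeated fits (a
Bayes-factor comparison); `consensus_loop()` iterates fit -> VI-centroid ->
Munkres alignment -> frequency prior until the consensus partition repeats
exactly (VI = 0), the strictest convergence rule that can be checked
exactly, with a 10-iteration cap; `fit_subject()` seeds each
subject's fit with the consensus concentrated at level 3 and keeps the
VI-centroid of five fits. All trial counts are configuration, scaled down
in tests and the demo pipeline.

Frequency priors are floored at `0.01 / k` before renormalisation so a
block that never appeared for a node is not permanently locked out of the
categorical prior.

The modular baseline is deterministic Newman leading-eigenvector bisection
with Kernighan-Lin single-node refinement on the gamma-scaled weighted
modularity matrix, swept over gamma 0.5..4.0 in 0.01 steps (351
partitions), then matched to the WSBM consensus by community count and VI
(`match_to_k()`); subjects without a k-community sweep partition receive a
typed exclusion signal rather than an error, so cohort-level code can
count and report exclusions. Sweep
ties resolve to the lowest gamma; all other ties in the package resolve to
the lowest index.

## Generative evaluation

`evaluate_model()` samples synthetic networks from fitted parameters,
binarizes them, and compares four binary node statistics against the
empirical network with the Kolmogorov-Smirnov statistic: degree, local
clustering, unnormalized shortest-path betweenness, and node Euclidean
distance. KS energy is the *mean* of the four components, not the maximum,
so no single statistic dominates. "Node Euclidean distance" is read as the
mean distance from a node to its connected neighbours; a `total` switch is
provided because the quantity is ambiguous in prose. The permuted-parameter
null (`permuted_model()`) applies one random permutation jointly to the
(rate, mean, variance) triplets of the upper-triangle-plus-diagonal,
preserving the parameter multiset and matrix symmetry. Evaluation uses
binary statistics only: the Normal weight family cannot rule out negative
weights, which is also why sampled weights are clipped at a small positive
floor (default 1e-6).

## Lifespan trend machinery

Block-interaction strengths (`block_summary()`, total mode conserving the
subject's total strength exactly) are residualized on nuisance covariates
(sex and total network strength by default, motion optional; the outcome
variable is residualized, not the age regressor) and
regressed on age under three families: linear, quadratic, and the Poisson
curve `b0 + b1 * age * exp(-b2 * age)`. The Poisson curve profiles `b2`
over a 16-point log-spaced grid in [1e-3, 1] and refines the best point by
1-D optimisation. Model choice uses leave-one-out RMSE; LOO predictions are
exact for the OLS families (hat-matrix identity) and grid-restricted for
the Poisson curve (the shape parameter is re-selected per fold from the
grid via SSE downdates — a documented compromise that keeps permutation
tests tractable).

Two deliberate choices:

* **Parsimony margin.** A more complex family must beat the simpler one by
  more than 2% relative LOOCV RMSE. As `b2 -> 0` the Poisson curve nests a
  near-linear shape, so under genuinely linear truth the raw comparison is
  a coin flip between equivalent fits; the margin restores consistent
  selection while leaving real curvature (which wins by large margins)
  untouched.
* **Permutation statistic.** `perm_pvalue()` permutes age and recomputes
  the LOOCV R^2 of the *already selected* family
  (`p = (1 + #(perm >= obs)) / (1 + n_perm)`); model selection is not
  re-run per permutation, keeping the null hypothesis well-defined and the
  cost linear in the permutation count.

R^2 is deliberately the uncentered variant
`1 - sum((y - y')^2) / sum(y^2)`; it can be negative and is not clamped,
which differs from the conventional centered R^2. Bonferroni thresholds are
`0.05 / m` with the *reported* alpha rounded to one significant figure
(0.0009 at m = 55, 0.0004 at m = 114); masks use the exact threshold.

Community-structure change is additionally summarised as vectors: the
upper-triangle-plus-diagonal of the k x k block matrix (length
`(k^2 - k)/2 + k`, 55 at k = 10), with the WSBM consensus vector the
elementwise product of predicted mean weight and presence probability, and
per-subject vectors compared by cosine similarity and city-block distance
before entering the same regression machinery. Mean-strength block matrices
are used there to damp community-size effects.

## The synthetic cohort generator

`generate_cohort()` emulates a lifespan connectome cohort: 114-node bilateral
networks (left nodes first, homotopic partner `i <-> i + n/2`, partners
sharing a block), k = 10 planted blocks with sizes 6-16 nodes, Poisson
edge existence and Normal edge weights per block pair at ~25-30% binary
density, ages uniform over 6-85 years (uniformity maximises design
leverage for trend recovery in a community-style sample), balanced sex, and
folded-Normal motion. The default affinity pattern is mostly assortative
with one disassortative block and one core-periphery motif; the
within/between weight-mean gap is about 3 pooled SD, chosen to make planted
recovery nontrivial but feasible — no empirical block-pair SDs are
available to copy, so this is a package choice, made once. Age trends per block pair are
`none`, `linear` (centred on the age midpoint), inverted-U `quadratic`
(peaking at a configurable age, zero at the range edges), or a
`poisson_curve`; sex adds a constant weight offset and motion subtracts a
scaled one. Node coordinates sit on a mirrored, jittered 3-D grid in mm
(left x < 0), sufficient for the distance-binned representative matrix and
the compactness/laterality statistics.

What the generator does **not** emulate: tractography geometry (distance is
Euclidean between centroids, not streamline length), weight distributions
with realistic skew (weights are clipped Normal), spatial autocorrelation
of parcels, and any dependence between motion and age. A green recovery
test therefore establishes that the algorithms behave correctly in the
stated world, not that empirical lifespan effect sizes are reproduced;
those derive from hundreds of subjects and hundreds of stochastic fits
per network and are out of reach at desk scale.

One interaction worth knowing: residualizing on total network strength
removes any planted trend whose block dominates total strength — by
construction, not by error. Recovery worlds therefore plant trends on
blocks that are a small share of the network, which is also the regime the
real analysis operates in (one block pair among 55).

## Degenerate inputs and edge cases

Empty networks fit with a warning (`k > 1` is then unidentified); singleton
or zero-spread modules get within-module z-scores of 0; empty block pairs
get existence rate 0 and a variance floor; k-means initialisation failures
fall back to random labels; permutation p-values are never 0 by the `+1`
convention; constant outcomes select the linear family by the tie rule.
Matrix symmetry is checked to 1e-8 with the offending entry named.

## Known limitations

* No degree correction, overlapping blocks, or non-Normal weight families;
  the classic WSBM limitations (poor clustering-coefficient reproduction,
  possible negative sampled weights) carry over by design.
* Inference is variational (no MCMC); evidence comparisons are lower-bound
  differences, not exact Bayes factors.
* The bootstrap-stability and consensus machinery fixes k; re-estimating k
  per bootstrap draw is not supported.
* LOOCV for the Poisson curve is grid-restricted per fold, as described
  above.
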