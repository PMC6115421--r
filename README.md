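# brainblocks

Community detection for weighted structural brain networks with the
**weighted stochastic block model (WSBM)**, plus everything needed to take a
cohort of connectomes from adjacency matrices to lifespan trend tables:
consensus fitting, a deterministic modularity baseline, generative model
evaluation by KS energy, community-conditional node statistics, and
permutation-based age-trend inference. A synthetic-cohort generator with
planted block structure makes the whole pipeline testable end to end.

## Who this is for

Network-neuroscience researchers who want community structure that is not
restricted to modular (densely intra-connected) organisation. The WSBM
treats nodes in a block as *stochastically equivalent*: per block pair
`(r, s)` an edge exists with a truncated-Poisson draw
(`P(edge) = 1 - exp(-theta_rs)`) and carries a Normal weight
`N(mu_rs, sigma2_rs)`. That parameterisation captures assortative,
disassortative, core-periphery and mixed mesoscale patterns that
modularity maximization cannot represent.

## What the package implements

| Stage | Functions |
| --- | --- |
| Synthetic bilateral cohorts (planted blocks, age trends) | `default_cohort_config()`, `generate_cohort()`, `write_cohort()` |
| Variational-Bayes WSBM | `fit_wsbm()`, `sample_network()`, `log_evidence()` |
| Representative matrix (distance-binned constrained average) | `build_representative()`, `subset_cohort_ages()` |
| Staged consensus workflow | `stage1_fit()`, `stage2_refine()`, `select_k()`, `consensus_loop()`, `fit_subject()` |
| Partition comparison | `vi_distance()`, `nmi()`, `find_centroid()`, `align_partitions()` |
| Modularity baseline (gamma sweep) | `spectral_modularity()`, `gamma_sweep()`, `match_to_k()` |
| Generative evaluation (KS energy) | `evaluate_model()`, `permuted_model()`, `modular_as_generative()` |
| Community metrics | `participation_coefficient()`, `within_module_z()`, `node_assortativity()`, `laterality_ks()`, `top_degree_dispersion_icc()`, `compactness()`, `versatility()`, `versatility_difference_test()` |
| Lifespan trends | `block_summary()`, `consensus_vector()`, `fit_trend()`, `select_trend()`, `perm_pvalue()`, `bonferroni_mask()`, `lifespan_pipeline()` |
| Pipeline / CLI | `run_pipeline()`, `read_config()`, `exec/brainblocks` |

See `vignettes/wsbm-connectome-methods.Rmd` for the model, the numerical
choices, and what the synthetic world does and does not emulate.

## Worked example

Generate a synthetic cohort, build a young-adult representative matrix,
select k by Bayes-factor comparison of mean log-evidence, derive a
consensus partition, score the generative fit, and regress block strengths
on age:

```r
library(brainblocks)

cfg    <- default_cohort_config(n_subjects = 30, n_nodes = 60,
                                k_planted = 4, rng_seed = 1)
cohort <- generate_cohort(cfg)
young  <- subset_cohort_ages(cohort, 25, 35)
rep_mat <- build_representative(lapply(young$subjects, `[[`, "connectome"))
#> <connectome> 60 nodes, binary density 0.314, total strength 91.69

select_k(rep_mat, k_range = 2:6, n_fits = 10, seed = 2)$table
#>   k mean_log_evidence
#> 1 2         -249.9898
#> 2 3         -182.0879
#> 3 4         -136.7034   <- planted k wins the Bayes-factor comparison
#> 4 5         -150.0921
#> 5 6         -161.0314

cons <- consensus_loop(rep_mat, 4, n_fits = 20, seed = 3)
#> <consensus_result> k = 4, converged after 2 outer iterations
nmi(cons$partition, cohort$truth)
#> [1] 1

fit <- stage1_fit(rep_mat, 4, n_trials = 25, seed = 4)
evaluate_model(fit$params, cons$partition, rep_mat,
               n_replicates = 100, seed = 5)$mean_energy          # intact
#> [1] 0.140
evaluate_model(permuted_model(fit$params, seed = 6), cons$partition,
               rep_mat, n_replicates = 100, seed = 5)$mean_energy # null
#> [1] 0.313

ls <- lifespan_pipeline(cohort, cons$partition, consensus_vector(fit$params),
                        n_perm = 199, seed = 7)
head(ls$block_trends[order(ls$block_trends$p), c(1, 2, 3, 8, 9)], 3)
#>   block_i block_j         model    loocv_r2    p
#> 5       2       2     quadratic  0.01378601 0.03
#> 8       3       3 poisson_curve  0.02423770 0.06
#> 4       1       4        linear -0.06837122 0.20
```

Reading the numbers: the consensus recovers the planted 4-block partition
exactly (NMI = 1); the intact generative model reproduces the empirical
binary statistics far better than its parameter-permuted null (KS energy
0.140 vs 0.313, lower is better); and with no planted age trend in this
cohort, no block pair survives the Bonferroni mask (`ls$bonferroni$alpha`
is 0.005 for the 10 block pairs), as it should.

## Command line

```sh
# flat key: value config; see ?run_pipeline for recognised keys
Rscript exec/brainblocks run-all --config demo.cfg --seed 7 --out runs/demo
```

Every stage writes its outputs plus a JSON provenance sidecar (seeds,
parameters, package version) into the run directory.

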