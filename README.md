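# percnet

Percolation-based targeted-attack analysis of functional brain connectomes.

Functional connectomes — networks whose nodes are brain regions and whose
edge weights are Pearson correlations between regional fMRI time series —
degrade in characteristic ways under neurodegenerative disease. This package
implements a complete analysis pipeline for asking *which node failures turn
a healthy network into a diseased-looking one*: proportional-density
thresholding, a weighted graph-quantifier battery, optimal-percolation
(collective influence) node ranking, basis/iterative/random node-removal
attacks, and a progression model that counts how many targeted attacks a
healthy network withstands before its quantifiers reach the diseased
baseline. It is aimed at researchers analyzing small-animal or human
resting-state connectivity matrices at the ~100-region scale, and it ships
a synthetic two-group cohort generator so the whole pipeline runs and is
tested without any subject data.

## The model in brief

- **Thresholding.** Each network is reduced to graph density
  d = E/[n(n−1)/2] by keeping the E = round(d·n(n−1)/2) strongest edges
  (negatives removed first). At n = 90, d = 0.10: E = 401, realized density
  0.1001, average degree 8.911.
- **Quantifiers.** CPL, global efficiency, radius, diameter (all over
  finite distances only, edge length = 1/weight), largest cluster size,
  Louvain modularity, transitivity, assortativity, small-world σ; nodal
  degree, strength, betweenness, eigenvector, clustering (Onnela), local
  efficiency, participation coefficient, and collective influence
  CI_ℓ(i) = (k_i−1) Σ_{j∈∂B(i,ℓ)} (k_j−1).
- **Attacks.** Nodes are removed (rows/columns zeroed) in order of a nodal
  quantifier computed once (*basis*) or recomputed after every removal
  (*iterative*), or uniformly at random (seeded ensemble); every global
  quantifier is snapshotted after each removal.
- **Progression.** Δ_t = q_disease(0) − q_control(t); the crossing step —
  the first sign change of Δ, linearly interpolated — is the number of
  targeted failures that makes the healthy network match the diseased one.
- **Statistics.** Wilcoxon rank-sum (normal approximation, tie + continuity
  corrected) with effect size r = |z|/√n, uncorrected, mirroring the
  convention of exploratory connectome batteries.

## Worked example

```r
library(percnet)

cohort <- generate_cohort(cohort_config(seed = 42))   # 17 + 17 subjects, 90 regions
prep   <- function(ms) threshold_proportional(normalize_matrix(group_average(ms)), 0.10)
ctrl   <- prep(cohort$control)
dis    <- prep(cohort$disease)
ctrl
#> <connectivity_matrix> 90 regions, 401 edges, state=thresholded, group=control, subject=group-average
c(control = largest_cluster_size(ctrl), disease = largest_cluster_size(dis))
#> control disease
#>      63      55

bet <- run_targeted_attack(ctrl, "iterative", "betweenness",
                           track = c("largest_cluster", "avg_betweenness"))
rnd <- random_attack_ensemble(ctrl, n_reps = 100, seed = 1,
                              track = "largest_cluster")
c(betweenness = attack_auc(bet), random = attack_auc(rnd))
#> betweenness      random
#>   0.1410935   0.4744180

baseline <- global_quantifiers(dis, which = c("largest_cluster", "avg_betweenness"))
progression_analysis(bet, baseline)$crossings["largest_cluster"]
#> largest_cluster
#>        4.666667
```

Read: the healthy group-average network holds a 63-region core and the
diseased one a 55-region core; an adaptive betweenness attack collapses the
healthy network ~3× faster than random failure (smaller area under the
normalized largest-cluster curve), and after fewer than five such targeted
removals the healthy network's largest cluster has already degraded to the
diseased baseline.

The `analysis/` directory holds numbered drivers that run the same pipeline
end to end and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort CSVs + atlas
Rscript analysis/02_preprocess.R    # group averages, thresholding, BrainNet export
Rscript analysis/03_quantify.R      # global + nodal quantifier tables
Rscript analysis/04_group_stats.R   # rank-sum comparison table
Rscript analysis/05_attacks.R       # all attack-scheme trajectories
Rscript analysis/06_progression.R   # baseline-crossing analysis
```

## Documentation

The methods vignette (`vignettes/connectome-percolation.Rmd`) documents the
model, the conventions (finite-pair distance metrics, rounding and
tie-breaks, the Onnela clustering choice), the synthetic cohort generator
and its calibration, and known limitations.
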