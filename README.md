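# ulsl — unified latent and similarity learning for multi-omics subtype discovery

`ulsl` identifies molecular subtypes from two or more omics views (e.g. mRNA
expression, DNA methylation, miRNA expression) measured on the same samples.
Instead of freezing a fused similarity network before clustering, or
factorizing the views without regard to sample-graph structure, it learns
both jointly: a shared latent representation H and a row-stochastic
sample-similarity graph Z regularize each other inside one objective,

```
min  Σ_v ||X⁽ᵛ⁾ − W⁽ᵛ⁾H||²_F  +  α||Z − A||²_F  +  β Tr(H L_Z Hᵀ)
s.t. ||w_j⁽ᵛ⁾||² ≤ 1,   0 ≤ z_ij ≤ 1,  z_iᵀ1 = 1
```

where A is a reference graph built once by similarity network fusion of the
per-view kernels, and L_Z is the Laplacian of the learned graph. The blocks
are updated alternately — ADMM with unit-ball columns for each W⁽ᵛ⁾, an exact
Sylvester solve for H, and row-wise Euclidean projections onto the
probability simplex for Z — so the objective is non-increasing. Subtypes
come from spectral clustering of Z, with the eigengap heuristic or the gap
statistic to choose the number of clusters. A calibrated synthetic
multi-omics generator (each view separates only three of four subtypes, so
only integration resolves all of them) makes the whole pipeline testable
without any downloads.

For who: anyone clustering multi-omics cohorts (TCGA-style matrices,
features × samples) or benchmarking integrative clustering methods.

## Worked example

```r
library(ulsl)

cfg <- sim_config(n_samples = 120, features_per_view = c(300, 200, 150),
                  signal_fraction = 0.10, seed = 42)
dataset <- simulate_multiomics(cfg)
dataset
#> multi_omics dataset: 3 views, 120 samples
#>   view1: 300 features
#>   view2: 200 features
#>   view3: 150 features
#>   true labels: 30/30/30/30

fit <- ulsl_fit(dataset, ulsl_params(d = 20, seed = 42))
fit
#> ulsl fit: 120 samples, 3 views, d = 20
#>   alpha = 13.54, beta = 0.1
#>   57 sweeps, converged = TRUE, final objective = 237.518

cl <- spectral_cluster(fit$Z, k = 4, seed = 42)
table(cl$labels, dataset$true_labels)
#>      1  2  3  4
#>   1  0 30  0  0
#>   2  0  0  0 30
#>   3  0  0 30  0
#>   4 30  0  0  0
nmi(cl$labels, dataset$true_labels)
#> [1] 1
```

The fit report shows the effective graph-fidelity weight
(α = α₀·Σd_v/n = 2.5·650/120 ≈ 13.54), that the alternating optimizer
converged (relative objective change < 1e−5) after 57 sweeps, and the
contingency table shows every sample assigned to its true subtype (NMI = 1)
even though no single view can separate all four groups.

For file-based runs there is a pipeline and a CLI
(`inst/cli/ulsl.R`, subcommands `simulate`, `fit`, `cluster`, `evaluate`,
`grid`):

```r
run_pipeline(c("mrna.tsv", "meth.tsv", "mirna.tsv"), "out/",
             ulsl_params(d = 60, seed = 1), k_method = "gap")
# writes out/Z.tsv, out/H.tsv, out/labels.tsv, out/objective_trace.csv,
# out/report.json
```

Matrices are delimited text, features × samples, sample IDs in the header;
views are aligned on their common samples, zero-variance features dropped.

The methods vignette (`vignettes/ulsl-methods.Rmd`) documents the model,
the block updates, all tunable parameters, the synthetic-data design and its
calibration, and known limitations.

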