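# nbcoex

Consensus gene co-expression modules from multiple single-cell RNA-seq count
datasets, via a latent-variable negative-binomial model.

## What it does

Given K raw count matrices (genes × cells) sharing a gene index — different
patients, batches or platforms — `nbcoex` asks which genes are co-expressed
*consistently across all of them*. Each gene i gets one latent coordinate
z_i ∈ R^λ shared by every dataset, with a standard-normal prior; each cell
(j, k) gets an offset α_jk and a loading vector β_jk that absorb depth,
capture efficiency and batch effects. Counts follow

    x_ijk ~ NB(u_ijk, θ_ik),   log u_ijk = α_jk + β_jk' z_i,
    Var(x) = u + u²/θ,

and the model maximises the penalized joint log-likelihood

    Σ log f(x_ijk | z_i, α_jk, β_jk, θ_ik) + Σ_i log φ_λ(z_i)
      − Σ_k Σ_j δ_k ‖β_jk‖₁

by Monte-Carlo EM: per-gene Metropolis–Hastings chains sample the latent
posterior (E-step); per-cell L1-penalized NB regressions are refit by
coordinate descent and dispersions by method of moments (M-step). K-means on
the fitted coordinates yields consensus modules; BIC can choose λ.

The package also ships seeded simulators for two benchmark designs
(per-cluster NB batches, and a Splat-style gamma-Poisson generator with
lognormal batch factors and logistic dropout), clustering validity indices
(ARI, Calinski–Harabasz, Davies–Bouldin, Dunn), hypergeometric gene-set
enrichment with BH correction, weighted Jaccard module comparison,
MatrixMarket/CSV readers and writers, preprocessing filters, a pipeline
driver and a small CLI (`inst/cli/nbcoex.R`).

## Worked example

```r
library(nbcoex)

# two simulated datasets, 60 genes in 3 planted co-expression clusters
co <- generate_nb_cohort(n_sets = 2, n_genes = 60, n_clusters = 3,
                         cells_per_dataset = 100, seed = 7)
x <- co$collections[[2]]
x
#> dataset_collection: 60 genes x 2 dataset(s) [100, 100 cells]

fit <- nbcoex(x, fit_config(lambda_dim = 3, rng_seed = 11))
fit
#> nbcoex_fit: 60 genes in a 3-dimensional latent space; 2 dataset(s)
#>   EM iterations: 26 (converged)
#>   final penalized log-likelihood: -37416.9

modules <- cluster_latent(fit$embedding, n_clusters = 3, seed = 1)
adjusted_rand_index(modules$labels, co$true_labels)
#> [1] 1
```

The fit prints how many EM iterations ran and the final penalized joint
log-likelihood (higher is better; the trace is in `fit$loglik_trace`). The
adjusted Rand index of 1 means the three planted clusters were recovered
exactly. On real data you would start from `read_counts()` +
`apply_filters()`, pick λ with `select_lambda_bic()`, and summarise modules
per cell with `module_means()`.

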