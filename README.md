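# dynamelt

Dynamics-informed multigraph learning of protein melting temperatures in R.

Most machine-learning predictors of protein thermostability use sequence
and static structure and ignore protein *dynamics*, a key determinant of
conformational stability. `dynamelt` encodes equilibrium dynamics into
graph representations and learns the melting temperature T_m (°C) from
them. It is aimed at structural bioinformaticians who want
dynamics-derived residue-coupling graphs, a multigraph regression model
over them, and residue-level interpretability — all runnable offline on a
single CPU.

## What it computes

From an alpha-carbon trace, an anisotropic elastic-network model yields
normal modes (ω²_α, x⃗_α). Each mode is weighted by 1/ω²_α (equipartition),
and three symmetric residue-pair couplings summarize the mode ensemble:

* **co-directionality** — weighted average cosine between two residues'
  displacement vectors, C_ij = Σ_α ω_α⁻² cos∠(x⃗_iα, x⃗_jα) / Σ_α ω_α⁻²;
* **coordination** — distance invariance,
  C_ij = 1 − ½ Σ_α ω_α⁻² (û_ij·(x⃗_iα − x⃗_jα))²;
* **deformation** — largest eigenvalue of (F⁽ⁱʲ⁾)ᵀF⁽ⁱʲ⁾, where
  F⁽ⁱʲ⁾_mn = Σ_α x_imα x_jnα / ω²_α is the linear response of residue i to
  a unit force on residue j.

Seven thresholding schemes (per-protein N / SIGMA / CONT / PAIR and
dataset-wide DN / DSIGMA / DCONT) turn coupling matrices into unweighted
graphs. Multigraph samples (contact + the three dynamical dimensions over
one node set) feed one of three graph feature extractors — S1 (single
graph convolution), M1 (independent convolution per dimension), or M2 (a
multi-dimensional graph convolution with cross-dimension attention
b_gd = softmax_g tr(W_gᵀ M W_d)) — combined with an optimal-growth-
temperature branch and a batch-normalized regression head. Training uses
AdamW (lr 0.01, weight decay 0.01), 30 epochs, batch 64, 10-fold
cross-validation with per-fold best-validation-epoch selection. Laplacian
centrality (relative drop of Σλ² on node deletion) profiles residues, and
a paired bootstrap compares models. A deterministic synthetic-structure
generator makes everything testable without downloads.

## Worked example

```r
library(dynamelt)

s     <- make_helix(40)                          # ideal 40-residue helix
modes <- compute_modes(build_hessian(s, cutoff = 15))
modes
#> <dyn_modes> 114 modes over 40 residues; omega^2 in [0.01964, 18.98]

coord <- coordination(modes, s)
round(coord$values[1:4, 1:4], 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 1.000 0.595 0.624 0.736
#> [2,] 0.595 1.000 0.604 0.713
#> [3,] 0.624 0.604 1.000 0.632
#> [4,] 0.736 0.713 0.632 1.000

# 1CONT threshold: as many coordination edges as 12-A contact edges
es <- apply_threshold(coord, threshold_spec("CONT", 1), structure = s)
es
#> <dyn_edge_set> type=coordination, 40 nodes, 252 edges

prof <- laplacian_centrality_profile(es, protein_id = "helix40")
head(round(prof$values, 3), 8)
#> [1] 0.004 0.019 0.040 0.046 0.048 0.049 0.050 0.060
```

114 retained modes is 3n − 6 for n = 40 (six rigid-body modes discarded).
Coordination values near 1 mark pairs whose distance barely fluctuates
across the mode ensemble; the 1CONT edge set has exactly the contact-graph
edge count (252). The centrality profile rises away from the helix
terminus: end residues disconnect little of the graph's Laplacian energy,
interior residues more.

Training on the synthetic study (400 proteins, labels
`20 + 0.5*OGT + 30*mean-coordination + N(0, 2²)` °C):

```r
dataset <- make_labeled_dataset(fixture_config(seed = 7))
cv <- train_model(dataset, model_config(extractor = "M2", seed = 3))
cv
#> <dyn_model_cv> M2 on {contact, codirectionality, coordination, deformation}: 10 folds
#>   out-of-fold: PCC 0.917, RMSE 3.821 C, MAE 2.653 C, R2 0.839
#>   released model: fold 7 (validation RMSE 1.993 C)
```

An out-of-fold Pearson correlation of 0.917 with RMSE 3.8 °C means the
model recovered both the OGT prior and the graph-encoded coordination
signal to within about twice the 2 °C label noise floor.

A shell interface wraps the same functions
(`system.file("cli", "dynamelt", package = "dynamelt")`) with subcommands
`couplings`, `graph`, `centrality`, `fixtures`, `train`, `predict`,
`compare`.

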