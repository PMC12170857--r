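# spniche

Integration of multi-slice spatial omics data and discovery of clinically
relevant tissue niches.

Cohorts of spatially resolved transcriptomics sections come with two
entangled problems: slice-specific batch effects that break any joint
clustering, and the gap between spot-level molecular maps and slice-level
clinical outcomes. spniche is an R implementation of a dynamically pruned
variational graph autoencoder with a mixture-of-Gaussians latent prior
that addresses both, aimed at computational biologists working with
Visium-class multi-sample datasets.

## Method at a glance

* **Unified graph.** Spots of all slices form one graph: intra-slice
  spatial neighbours (kNN, or a radius calibrated to mean degree 5–6)
  plus inter-slice mutual nearest neighbours on 50 expression PCs.
* **Model.** A two-layer multi-head graph-attention encoder (512 → 10,
  3 heads) parameterizes q(z | X, A); the prior is a K-component Gaussian
  mixture, p(c) = 1/K, p(z | c) = N(u_c, σ²_c I). A shared linear decoder
  with *slice-specific batch normalization* (γ_i, β_i) reconstructs
  expression, an inner-product decoder sigmoid(zᵀz) reconstructs the
  graph. The objective is
  `L = L_expr + δ·L_adj + φ·D_KL(q(z,c|X,A) ‖ p(z,c))`.
* **Dynamic graph evolution.** After 300 pretraining iterations and EM
  initialization of the mixture, training alternates (it = 0, 1, 2) with
  removal of every edge whose endpoints fall in different mixture
  components, so message passing sharpens toward within-niche
  neighbourhoods.
* **Clinical head.** Each slice is summarized per cluster by ten
  statistics of a shared 2-D UMAP embedding (mean/variance/max/min per
  axis + within- and cross-slice proportions), pooled by attention over
  the ten measures, and fed to a Cox layer (partial likelihood over
  non-censored slices) or softmax layer. The transposed head weights
  rank niches by clinical importance; cross-validation is slice-level
  (random folds for Cox, leave-one-out for classes).
* **Zero-shot transfer.** A frozen encoder embeds a new slice on its own
  spatial graph; labels transfer by majority vote among the 5 nearest
  reference spots in latent space.
* **Offline testing.** A negative-binomial generator plants spatial
  domains, marker blocks, batch shifts, and composition-driven survival
  or class labels, so the whole pipeline is testable without downloads.

## Worked example

```r
library(spniche)

# simulate a 3-slice cohort with 4 planted domains and batch shifts
sim    <- simulate_slices(sim_config(L = 3, seed = 1))
slices <- lapply(sim$slices, normalize_log)
ds     <- assemble_dataset(slices, select_common_hvgs(slices))

# unified graph: spatial kNN within slices + MNN across slices
intra <- lapply(seq_len(ds$L) - 1, function(i)
  build_intra_edges(ds$S[ds$slice_of == i, ], "knn", k = 6))
graph <- unified_graph(intra, build_mnn_edges(ds), ds$slice_of)
graph
#> <unified_graph> 900 spots, 5188 edges (2988 intra, 2200 inter), it=0

estimate_k(ds$X)    # mixture size from the data spectrum
#> [1] 5

fit <- integrate_slices(ds, graph, train_config(seed = 1))
fit$graph_history   # pruning trims cross-niche edges each iteration
#> [1] 5188 4076 3728 3063

truth <- unlist(sim$truth$domains)
ari(fit$assignments, truth)
#> [1] 0.827
lisi(fit$z, ds$slice_of)$mean          # iLISI ~ 2.4: slices well mixed
#> [1] 2.373
```

The fitted latent recovers the planted domains (ARI 0.83 against the
generator's truth) while mixing the three slices (iLISI 2.4 out of a
maximum of 3, versus 1.15 on uncorrected principal components). The same
`fit` object feeds `slice_statistics()` + `fit_clinic_head()` for
survival/classification, `build_reference()` + `embed_query()` +
`transfer_labels()` for zero-shot annotation, and `denoise_expression()`
for reconstruction.

A thin command-line wrapper covering the same workflow
(`simulate`, `prep`, `graph`, `integrate`, `cluster`, `clinic`,
`transfer`, `metrics`) is installed at `inst/cli/spniche.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/spniche.R", package="spniche"))')" simulate --out run1 --seed 1
```

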