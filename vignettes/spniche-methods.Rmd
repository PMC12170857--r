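---
title: "Model and methods behind spniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind spniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spatially resolved omics experiments profile tissue sections ("slices") as
spot-by-gene matrices with known 2-D coordinates. Cohort studies collect
many slices from many patients, and two obstacles stand between the raw
data and biology: slice-specific technical variation (batch effects) that
confounds any joint analysis, and the gap between spot-level molecular
structure and slice-level clinical outcomes such as survival. spniche
addresses both: it learns a batch-corrected latent space in which spots
from all slices are comparable and cluster into spatial niches, and then
summarizes each slice by the geometry of its niches so that niches can be
ranked by their association with survival or class labels.

# The probabilistic model

Spots from all slices are nodes of one unified graph. Within a slice,
spots are linked to their spatial nearest neighbours (k-nearest by
default, or a radius calibrated by bisection so the mean degree lies in
[5, 6]). Across slices, spots are linked when they are mutual nearest
neighbours (MNN) in expression space; we compute MNN on the top 50
principal components of the gene-standardized joint matrix under cosine
distance, which denoises and follows common practice for anchor finding.

On this graph a variational graph autoencoder learns a latent code $z_u
\in \mathbb{R}^{10}$ per spot. The generative story is a mixture of
Gaussians: a component $c \sim \mathrm{Cat}(1/K)$, then $z \sim
\mathcal{N}(u_c, \sigma_c^2 I)$, then the expression profile and the
adjacency are both decoded from $z$. The encoder is a two-layer
multi-head graph-attention network (widths 512 and 10, 3 heads). Per
head, the attention that node $i$ pays to neighbour $j$ is a softmax over
$\mathcal{N}(i)$ (self-loop included) of
$\mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j])$ with negative slope
0.2; the layer output is the ELU of the head-averaged attention-weighted
neighbour sum. The second stage runs two parallel attention heads
producing the posterior mean and log-variance; these moment heads use an
identity activation (an ELU there would floor the log-variance at $-1$
and truncate the mean), which is the usual variational-autoencoder
convention.

Decoding is deliberately simple. A single shared linear map $h = Wz + b$
returns to gene space, and each slice then applies its own batch
normalization with learned scale $\gamma_i$ and shift $\beta_i$: the
slice's technical offset is absorbed by its normalizer, so the latent
space is pushed to encode what slices share. The graph is decoded as
$\mathrm{sigmoid}(z_u^\top z_v)$.

Three losses are combined: a per-slice mean-squared reconstruction error
(averaged per element so slices of different sizes weigh equally), the
full-matrix binary cross-entropy between observed and reconstructed
adjacency (mean over all $n^2$ ordered pairs; above 5000 spots an
unbiased positive + sampled-negative estimate rescaled to the same
convention), and the KL divergence from the mixture prior to the
mean-field posterior $q(z, c) = q(z)\,q(c)$. The KL has a closed form:
responsibility-weighted Gaussian KLs plus the categorical term
$\sum_c \gamma_c \log(\gamma_c K)$, with responsibilities evaluated at
the posterior mean and treated as constants in the gradient (the
coordinate-ascent treatment standard for mixture-prior VAEs).

## Scaling the KL term

The reconstruction loss is a per-element mean while the KL is a sum over
spots and latent dimensions; the two conventions differ by a factor of
$n \times m$, and using them together verbatim lets the KL dominate by
several orders of magnitude — in our experiments the latent space then
collapses into a single component. The training objective therefore
normalizes the KL by $n \cdot m$, which restores exactly the balance the
sum-convention objective has; this is a pure rescaling of the KL weight
$\varphi$, whose default stays 1. Users who want a stronger or weaker
mixture prior should move $\varphi$, not the conventions.

# Training and graph dynamic evolution

Training has three phases. (i) Pretraining: 300 full-batch iterations of
the reconstruction terms only. (ii) Mixture initialization: a
diagonal-covariance Gaussian mixture is fitted to the pretraining latent
by EM (mclust; k-means fallback), and its means and variances initialize
the prior components. (iii) Dynamic training: for outer iterations
$it = 0, 1, 2$, the full objective is optimized; each spot is assigned to
its most responsible component at the posterior mean; every graph edge
whose endpoints disagree is removed; and training continues on the pruned
graph. Pruning is removal-only, so edge counts are non-increasing, and
the loop stops early if a pass removes nothing. A `fixed_graph` switch
disables pruning for ablation.

Two departures from a naive reading deserve a note:

* **Mixture refresh.** The slice-specific batch-normalizing decoder makes
  the objective invariant to the overall scale of $z$, which therefore
  drifts during training. Mixture components updated only by gradient are
  fitted at the pretraining scale and lose track of the shrinking latent
  — empirically every spot ends in one component while the latent itself
  remains cleanly clustered. We therefore re-estimate the mixture by EM
  on the current evaluation-mode latent at the end of each outer
  iteration, immediately before assignment and pruning; gradients still
  fine-tune the components within each cycle.
* **Convergence rule.** Each outer iteration runs at most `inner_epochs`
  gradient steps but stops earlier once the 50-epoch windowed mean of
  the loss improves by less than $10^{-4}$ relative — "trained until
  convergence" operationalized. The default budget of 300 epochs per
  cycle was chosen by comparing shorter and longer budgets on the
  default synthetic conditions: domain recovery saturates well before
  it, but the encoder's robustness to an *unseen* batch — measured as
  zero-shot transfer accuracy to a held-out slice, which the test suite
  exercises — keeps improving up to roughly this budget and only
  marginally beyond. The longer run remains one configuration flag away.

The optimizer is Adam (learning rate $10^{-3}$, weight decay
$5\times10^{-4}$ on weight matrices), full batch. One master seed fans
out to independent child seeds for initialization, reparameterization
noise, EM, fold assignment, and UMAP, so a fit is reproducible
end-to-end; the test suite asserts byte-identical latents across
repeated runs.

# From niches to clinical outcomes

After integration, clusters of the latent space are the candidate
niches. A single UMAP embedding is fitted jointly on all spots (uwot,
seeded), so slices and clusters share one 2-D geometry. Slice $i$ and
cluster $k$ are then summarized by ten statistics: the mean, population
variance, maximum and minimum of each UMAP axis over the slice's
cluster-$k$ spots, the cluster's proportion within the slice, and its
proportion among all spots of the other slices. A cluster absent from a
slice contributes ten zeros. Because coordinates and proportions live on
incommensurate scales, each of the $10K$ features is z-scored across
slices before entering the head (constant features map to zero); the
fitted centering is stored and reapplied at prediction time.

The ten $K$-vectors are pooled by attention: measure $j$ receives weight
$\lambda_i^j = \mathrm{softmax}_j(a_j^\top \mathrm{vec}(F_i))$ and the
slice representation is $r_i = \sum_j \lambda_i^j f_i^j \in
\mathbb{R}^K$. A linear head maps $r_i$ to a score: for survival, the
negative Cox partial likelihood over the non-censored slices (risk sets
by time, Breslow handling of ties, censored slices contribute to risk
sets only); for classes, a softmax cross-entropy. The transposed head
weights live in cluster space, so after fitting they read directly as
per-niche clinical importances. Optimization is full-batch Adam
(learning rate $10^{-2}$, 1000 epochs, plateau stop) from a
zero-symmetric start: attention logits begin at zero (uniform weights
over the ten measures) and sharpen only where the task finds signal.
The L2 penalty defaults to 0.2 — deliberately strong, because the head
has roughly $10^2 K$ parameters while a cohort contributes only tens of
slices; at weak regularization the head simply memorizes its training
slices and its held-out predictions carry no signal, whereas at the
default the cross-validated concordance reaches the level of the
generative oracle on the synthetic cohorts the test suite runs.

Cross-validation respects the slice as the sampling unit: random
slice-level folds for Cox (each fold must hold out at least two slices,
since a concordance index on one subject is undefined; a fold without
events is skipped with a warning), and leave-one-out for classification
with accuracy and AUROC (macro-averaged when multiclass) computed from
the held-out predictions. The shared UMAP is fitted once on all slices:
the unsupervised stage never sees the labels, so there is no label
leakage; refitting it per fold would only add embedding variance between
folds.

# Zero-shot label transfer

A trained encoder can annotate a new slice without retraining. The
reference bundle freezes the encoder, the gene list, the normalization
target, and the intra-slice graph rule. A query slice is normalized the
same way, restricted and reordered to the reference genes (missing genes
are zero-filled — log-space zero means unexpressed — with a warning;
under 50% overlap is an error), given its own intra-slice spatial graph
(no query–reference edges: the encoder is frozen, so anchors would have
nothing to align), and encoded in evaluation mode. Labels then transfer
by majority vote among the k = 5 nearest reference spots in latent
space, with the vote fraction as a confidence and ties resolved by the
single nearest neighbour. So that reference and query pass through the
*identical* map, the bundle stores reference latents recomputed per slice
under the same intra-only graph rule — embedding a training slice
therefore reproduces its stored reference latent exactly, a property the
test suite asserts.

# The synthetic data generator

All tests run offline on simulated cohorts designed to exercise every
pipeline stage. Each of `L` slices lays `K_true` domains out as
horizontal strips (cortical-layer-like) or Gaussian blobs
(tumor-region-like), with per-slice domain proportions drawn from a
Dirichlet so composition varies across the cohort. Every domain owns an
exclusive block of marker genes (default 50) whose log-mean rises by the
domain effect (default 1.0) inside the domain; every slice adds an
independent gene-wise log-normal batch shift (default sd 0.3); counts
are negative binomial (dispersion 0.3) around log-normal baseline means.
Slice-level outcomes follow the planted composition: exponential
survival times with hazard $\exp(\beta_{sim} \cdot p_{i,\text{target}})$
and calibrated independent censoring, or binary classes by thresholding
the target-domain proportion at its cohort median.

Default conditions are 3 slices × 300 spots × 600 genes with 4 domains
for integration (a 4th slice from the same draw serves as the zero-shot
query), and 24 slices × 120 spots × 300 genes with $\beta_{sim} = 3$ and
10% censoring for the clinical stage — sizes chosen so a full run
completes in minutes on a laptop core while keeping every planted effect
comfortably detectable.

One property of the survival generator deserves emphasis. With
exponential event times, two slices whose log-hazards differ by $d$ are
concordant with probability $e^d/(1+e^d)$, so at $\beta_{sim} = 3$ and
proportions in $[0,1]$ *no* predictor — including the true hazard — can
exceed a pooled concordance of about 0.73 (reached only when the cohort
splits into maximally separated composition groups); exchangeable
Dirichlet compositions sit far below that. The clinical test cohort is
therefore *designed*: half the slices are rich in the target niche
(Dirichlet concentration $(5,1,1,1)$) and half poor ($(0.3,2,2,2)$),
the case/control contrast a survival cohort would be assembled around.
Reported concordances on synthetic cohorts should always be read
against this generator ceiling, not against 1. What passing these tests shows is that the
machinery recovers structure it is pointed at under controlled batch
effects and outcome links; what it cannot show is robustness to the ways
real tissue violates the generator — spatially smooth (not blockwise)
expression gradients, segmentation artifacts, uneven spot densities,
cell-type mixtures within spots, or clinical signal carried by features
other than niche composition.

# Numerical choices and edge cases

* Attention logits are max-subtracted per neighbourhood before the
  softmax; the log-variance head is clamped to $[-10, 10]$.
* Cross-entropy probabilities are clipped at $10^{-7}$; mixture
  responsibilities are computed in log space.
* Batch statistics use the population variance; a single-spot slice gets
  a variance floor of $\varepsilon = 10^{-5}$, making its normalized
  profile the learned shift $\beta_i$.
* Nearest-neighbour ties (spatial graphs, MNN, label transfer) break
  toward the lowest spot index, keeping every graph deterministic.
* Spots in singleton clusters take silhouette width 0; NMI uses the
  arithmetic-mean normalization; LISI uses perplexity 30 over the
  3×perplexity nearest spots with the kernel bandwidth solved by
  bisection to entropy $\log(\text{perplexity})$.
* `estimate_k` counts eigenvalues of the gene-standardized Gram matrix
  above the Marchenko–Pastur bulk edge $(1 + \sqrt{n/m})^2$, clamped to
  $[2, 30]$ — the number of directions a pure-noise matrix of the same
  shape could not produce.
* In multi-omics mode, externally produced low-dimensional features are
  taken as `X` directly: normalization and HVG selection are skipped and
  the same graph, model and heads apply unchanged.

# Known limitations

The full-batch trainer holds the dense $n \times n$ adjacency
reconstruction in memory, which is comfortable to roughly 10–20k spots
but is not a path to atlas-scale corpora; mini-batch neighbour sampling
is out of scope. The Gaussian decoder models log-normalized expression,
not counts; there is no negative-binomial likelihood. Slices enter the
graph only through expression-space anchors — no 3-D geometric
alignment of sections is attempted. The clinical head sees slice-level
labels only and cannot exploit within-slice clinical heterogeneity, and
with small cohorts its cross-validated metrics retain substantial fold
variance.
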