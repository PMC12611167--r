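---
title: "Methods: multi-view graph convolution for spatial domain identification"
author: "spadom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view graph convolution for spatial domain identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spatial transcriptomics platforms (10x Visium, Visium HD, Stereo-seq,
Xenium, ...) measure a gene expression profile at thousands of spatially
indexed capture locations ("spots"). A central analysis step is
*spatial domain identification*: partitioning the spots into spatially
coherent regions with a shared expression program — cortical layers,
tumour compartments, olfactory bulb laminae. Expression alone is noisy
and sparse; spatial position alone carries no biology. `spadom` learns a
latent embedding that fuses both, then clusters it.

## Model overview

The model combines five pieces, trained jointly end to end:

1. **Spatial neighbour graphs.** Two undirected graphs over spots: a
   *mutual K-nearest-neighbour* graph (edge iff each spot is within the
   other's k nearest; captures local structure) and a *radius* graph
   (edge iff Euclidean distance ≤ r; captures structure at the scale of
   the platform resolution). Both enter graph convolutions through the
   symmetric normalization $\tilde D^{-1/2}(A + I)\tilde D^{-1/2}$,
   whose spectral radius is ≤ 1.

2. **Gene-expression enhancement by graph contrastive learning.** A
   cosine-similarity *feature graph* connects transcriptionally similar
   spots. A corrupted view is built by permuting the rows of the
   expression matrix while keeping the graph fixed (the standard
   topology-preserving corruption). A GCN encoder embeds the clean and
   corrupted matrices; a graph *deconvolution* decoder (operator
   $I + L$, the first-order inverse of the convolution filter $I - L$)
   reconstructs the input. The contrastive objective is a hinged
   triplet on per-spot cosine similarities,
   $L_{com} = \frac1N\sum_i \max(0,\ \alpha - s^{pos}_i + s^{neg}_i)$,
   with anchor = clean latent, positive = the anchor's
   decoder-roundtrip latent (a self-consistency target), negative = the
   corrupted-view latent.

3. **Three-view encoder with shared-weight co-convolution.** ReLU GCN
   stacks produce (i) a spatial view: separate stacks on the KNN and
   radius graphs, averaged; (ii) a feature view on the feature graph;
   (iii) a co-convolution view: one *shared* weight set applied to all
   three graphs, branch outputs averaged. A Gram-matrix consistency
   penalty $\|\tilde Z_{sc}\tilde Z_{sc}^\top - \tilde Z_{s_ac}\tilde
   Z_{s_ac}^\top\|^2_F + \|\tilde Z_{sc}\tilde Z_{sc}^\top - \tilde
   Z_{fc}\tilde Z_{fc}^\top\|^2_F$ (rows L2-normalized) aligns the
   pairwise-similarity structure of the co-convolution branches.

4. **View-level attention fusion.** Each view embedding is scored per
   spot by a shared two-layer map ($\tanh$ inner layer, linear
   projection) and the three scores are softmaxed *across views*, so
   each spot's fused embedding $Z$ is a convex combination of its three
   view embeddings. The softmax axis is the only choice that makes the
   weighted sum a per-spot convex combination.

5. **ZINB reconstruction + spatial regularization.** Three affine heads
   on $Z$ produce per-entry zero-inflation $\pi$ (logistic link), mean
   $\mu$ (exponential link, bounded pre-activation), and dispersion
   $\theta$ (softplus link) of a zero-inflated negative binomial; the
   reconstruction loss is the mean ZINB negative log-likelihood of the
   count matrix. The spatial regularizer pulls neighbouring spots
   together and pushes sampled non-neighbours apart in cosine space:
   $-\frac12[\mathrm{mean}_{pos}\log\sigma(s_{ij}) +
   \mathrm{mean}_{neg}\log(1-\sigma(s_{ij}))]$.

The total objective is $\lambda_1 L_{zinb} + \lambda_2 L_{com} +
\lambda_3 L_{con} + \lambda_4 L_{reg}$ with unit weights by default,
minimized by Adam (learning rate 1e-3, weight decay 5e-4). The final
embedding is clustered by seeded k-means++ (or a Gaussian mixture).

## Design choices where the design was open

Several pieces of this architecture admit more than one reading; the
package fixes them as follows.

**Contrastive loss form.** The raw difference form
$\mathrm{mean}(s^{pos} - s^{neg} + \alpha)$ is not a usable training
objective: minimizing it *decreases* positive similarity. `spadom`
trains the standard hinged triplet (above); the unhinged form is kept
as `cl_form = "literal"` for auditing, never for training.

**ZINB mixture.** The likelihood is the canonical mixture
$P(0) = \pi + (1-\pi)\,\mathrm{NB}(0)$,
$P(x>0) = (1-\pi)\,\mathrm{NB}(x)$, with the mean negative
log-likelihood as loss. Degenerate variants that assign no probability
mass to the inflated zeros, or that scale the log-likelihood by $\pi$,
are not likelihoods of any distribution and are not implemented.

**Input to the feature and co-convolutions** (`feature_input`). Two
candidates exist: the corrupted matrix itself, or the representation
learned by the contrastive module. The default is `"latent"` — the
clean-stream contrastive encoder latent — because a row-shuffled
corrupted matrix assigns every spot *another spot's* expression vector,
which destroys exactly the per-spot signal the clustering views must
preserve; the corruption exists to serve as a contrastive foil, not as
input features. This coupling also makes the contrastive module
load-bearing for the clustering path, which is why ablating it hurts.
`feature_input = "corrupted"` retains the alternative wiring.

**Contrastive pairs.** The positive sample is the anchor's
decoder-roundtrip latent (encode → deconvolve → re-encode): it shares
the anchor's content but has passed through the reconstruction
bottleneck, making agreement a self-consistency constraint. The
negative is the corrupted-view latent. With this design the two streams
keep separate encoder/decoder weights.

**Graph conventions.** "Each other's K nearest neighbours" is read as
*mutual* KNN (intersection); `knn_mode = "union"` gives the OR
symmetrization many toolkits use. Distance ties break by ascending spot
index, making every graph deterministic. Self-loops are added only
inside the normalization, never stored. The feature graph connects only
neighbours with strictly positive cosine similarity (orthogonal
profiles share no signal). The default radius is 1.2 × the median
nearest-neighbour distance, which on a regular lattice connects exactly
the first neighbour shell; k defaults to 6 (the hex first shell) and
`k = "auto"` scores a candidate grid by the mean silhouette of a
k-means clustering of a spectral embedding of the normalized adjacency
(an unsupervised score, usable without labels; an ARI mode exists for
benchmarking with known labels).

**Cluster count and algorithm.** Clustering is seeded k-means with
k-means++ initialization (deterministic, standard for latent-embedding
clustering); `method = "gmm"` fits a Gaussian mixture via mclust. The
number of clusters is supplied by the user, matching the usual protocol
of setting it to the known number of annotated domains.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 6 | mutual-KNN neighbours (hex first shell); `"auto"` searches 1–20 |
| `r` | 1.2 × median NN distance | radius-graph cutoff, platform units |
| `k_f` | 15 | feature-graph neighbours per spot |
| `alpha` | 0.5 | contrastive hinge margin (cosine units) |
| `lambda` | (1, 1, 1, 1) | weights of (ZINB, contrastive, consistency, regularizer) |
| `n_neg` | 5 | sampled non-neighbour pairs per spot for the regularizer |
| `lr`, `weight_decay` | 1e-3, 5e-4 | Adam settings |
| `epochs` | 200 | maximum epochs; plateau early stop (patience 20, tol 1e-4) |
| `dims_contrastive` | 128 → 64 | contrastive encoder widths (decoder mirrored) |
| `dims_view` | 64 → 64 | per-view GCN widths (2 layers) |
| `att_h`, `att_h2` | 32, 16 | attention scoring widths |

## Numerical choices

Input features are internally scaled by the global standard deviation
of the (normalized) expression matrix before entering the encoders, so
ReLU/tanh/exponential pre-activations start at order 1 under the
1e4-total-count normalization; the counts fed to the ZINB likelihood
are untouched. The ZINB mean head clips its pre-activation to ±12
before exponentiation; dispersion uses softplus plus a 1e-10 floor; all
likelihood logs carry 1e-10 guards. The ZINB likelihood and its
gradient are computed in one fused C++ pass; for integer counts ≤ 64
the gamma-function ratios use exact recurrence sums instead of
lgamma/digamma calls. Isolated nodes normalize to a unit self-loop.
k-means++ centres receive 1e-9 jitter to guard degenerate duplicate
centres. Every stochastic stage (initialization, corruption, negative
sampling, clustering) draws from a seed derived from one master seed,
and seeded helpers restore the caller's RNG state, so a fixed master
seed reproduces the label file byte for byte on one machine.

## The synthetic tissue generator

`simulate_tissue()` emulates a layered tissue: spots on a hex (Visium
6-neighbour) or square lattice; domains as contiguous horizontal bands
or nested concentric rings (rings are defined in a max-norm metric so
every ring stays lattice-connected); each domain owns a disjoint set of
marker genes whose negative-binomial mean is `marker_fold` × the
background `base_mu` inside the domain; counts are drawn from a ZINB
with dispersion `theta` and zero-inflation `pi0`. Three presets on a
20 × 30 hex lattice (600 spots, 4 bands, 150 genes, 10 markers per
domain, `base_mu` 1.5, `theta` 2) differ in difficulty: *easy* (fold 8,
π₀ = 0.1), *medium* (fold 3, π₀ = 0.3), *hard* (fold 2, π₀ = 0.5).

What the generator does **not** emulate: platform-specific technical
noise (spot swapping, diffusion, segmentation error), gene–gene
correlation beyond the domain programs, library-size gradients,
histology, or irregular tissue boundaries. Passing the recovery tests
on these fixtures therefore demonstrates that the machinery is
implemented correctly and can recover planted, spatially contiguous
expression programs — not that it matches any particular published
performance level on real tissue.

## Problem sizes used by the test suite

The suite exercises the full pipeline at desk scale: the easy preset
(600 spots, up to 200 epochs) for domain recovery; the medium preset
across 5 seeds × 5 model variants at 150 epochs for the ablation
ordering study (the full model converges on all seeds by ~150 epochs
under the default early-stopping tolerance); 120-spot fixtures for
determinism and artifact checks; 5-spot instances for the
finite-difference gradient verification.

## Known limitations

- The two spatial graphs nearly coincide on a regular lattice at the
  default k and r (both select the first neighbour shell), so the two
  spatial views differentiate mainly at tissue boundaries and on
  irregular spot layouts; on such data the single-spatial-view
  ablations can come close to the full model.
- Dense N × N matrices appear in the Gram consistency penalty and in
  graph normalization, so memory grows quadratically in spots;
  the intended scale is 10²–10⁴ spots.
- No spatial refinement is applied to the cluster labels after
  k-means; labels are whatever the embedding supports.
- The trainer is full-batch; no minibatching or GPU path.
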