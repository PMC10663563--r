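# spstack

Multi-slice spatial transcriptomics analysis in R: spot cell-type
deconvolution, joint spatial-domain identification across slices, rigid 3D
reconstruction of serial sections, and continuous 3D expression modelling
with a spatial-variability score.

Sequencing-based spatial platforms (e.g. 10X Visium) measure mixtures:
each capture spot contains mRNA from several cells. Consecutive sections
of one tissue block are additionally rotated, shifted, mirrored and
damaged on their slides, and different slices carry batch effects. spstack
addresses this end to end for analysts working with a single-cell
reference and one or more spatial slices.

## The models

**Deconvolution — `deconvolute()`.** Pseudo-spots are simulated from the
reference: cells per spot N<sub>c</sub> ~ N(μ<sub>c</sub>, δ<sub>c</sub>)
(default 10, 5), types per spot N<sub>t</sub> ~ N(μ<sub>c</sub>/2,
δ<sub>c</sub>/2), with per-spot type-sampling probabilities switching
among f<sub>t</sub>, the normalized 1/f<sub>t</sub> and the normalized
√f<sub>t</sub> (f<sub>t</sub> = reference type frequencies), then thinned
by exact multivariate-hypergeometric downsampling to the real slice's
depth distribution. A variational autoencoder (128–64–128) embeds
simulated and real spots in one latent space; a 3×512 MLP predicts
proportions (softmax) under the loss (1 − cos) + KL(truth ‖ pred); a
recovery head maps proportions back toward the latent; and the squared
maximum mean discrepancy between simulated and real hidden embeddings,
MMD²(U,V) with Gaussian kernel exp(−|u−v|²/σ), aligns the two
distributions.

**Spatial domains — `spatial_domains()`.** Per-slice k-nearest-neighbour
graphs (k = 6 for Visium) feed a five-layer Chebyshev graph-convolutional
network, y = Σ<sub>k</sub> T<sub>k</sub>(L̃) X θ<sub>k</sub> on the scaled
Laplacian L̃ = 2L/λ<sub>max</sub> − I, applied to cell-type compositions.
A cosine reconstruction loss, a neighbour-smoothness loss on the
16-dimensional latent, and an adversarial slice discriminator (total
objective α<sub>C</sub>L<sub>C</sub> + α<sub>S</sub>L<sub>S</sub> −
α<sub>D</sub>L<sub>D</sub>, defaults 1, 1, 0.5) produce batch-mixed latent
features; K-means on the pooled latent, monitored by the Davies–Bouldin
score, yields one domain vocabulary across all slices.

**Rigid alignment — `align_stack()`.** Each slice is aligned to the
previous one by maximizing a domain-agreement objective (AOF): mean
agreement of mutual k-nearest-neighbour pairs within a distance cut-off,
minus |n<sub>o</sub>/n<sub>j</sub> − 1|<sup>p</sup> on the non-overlap
fraction. The search over rotation θ, translation and mirror flip uses
differential evolution, re-deriving the neighbour structure at every
candidate; aligned slices are stacked at a chosen z spacing.

**3D expression — `fit_gpr()` / `bayes_factor()`.** A constant-mean
Gaussian process with covariance δ²·exp(−|x−x′|²/2ℓ²) plus noise models
one gene over the aligned 3D coordinates; hyperparameters maximize the
exact log marginal likelihood. Spatial variability is the Bayes factor
against the ℓ → ∞ limit (a constant-covariance model with no spatial
structure); BF > 1 indicates spatial variation. `build_mesh()` (alpha
shape + Loop subdivision) and `sample_mesh()` support surface predictions.

Simulation (`generate_reference()`, `simulate_pseudospots()`,
`generate_stack3d()`, `perturb_stack()`) and evaluation
(`deconv_metrics()`, `accuracy_score()`, `domain_metrics()`,
`asw_batch()`, `find_svgs()`, `grid_similarity()`, ...) make every stage
testable against known ground truth. See `vignettes/methods.Rmd` for the
full model descriptions and design choices.

## Worked example

A complete run on synthetic data with known truth (a few minutes on one
CPU):

```r
library(spstack)

# a 5-type single-cell reference with planted markers
ref <- generate_reference(n_types = 5, n_genes = 200, n_cells = 500,
                          marker_genes_per_type = 10, marker_logfc = 2,
                          seed = 1)

# pseudo-spots with known composition play the role of a measured slice
mix <- simulate_pseudospots(ref, n_spots = 500, seed = 2)
slice <- slice_data(mix$counts, cbind(runif(500, 0, 1000), runif(500, 0, 1000)))

fit <- deconvolute(ref, slice, n_sim_spots = 1000, n_markers_per_type = 50, seed = 3)
fit
#> <deconv_fit> 190 genes, 5 cell types, 256 training epochs
#>   final losses: E = 0.1680, R = 0.3268, MMD = 0.0009468

round(head(coef(fit), 3), 3)
#>       type1 type2 type3 type4 type5
#> spot1 0.046 0.012 0.362 0.562 0.018
#> spot2 0.023 0.028 0.696 0.141 0.113
#> spot3 0.571 0.078 0.112 0.191 0.050

deconv_metrics(coef(fit), mix$proportions)
#>    type       pcc      ssim       rmse        jsd
#> 1 type1 0.9238353 0.9122599 0.08391868 0.03766067
#> 2 type2 0.9214173 0.9088688 0.08297821 0.03253070
#> 3 type3 0.8976203 0.8898031 0.09002719 0.03677143
#> 4 type4 0.9258635 0.9042733 0.08351882 0.04526257
#> 5 type5 0.8918404 0.8579802 0.09490090 0.04820015
```

Each row scores one cell type across the 500 spots: the predicted spatial
pattern of every type correlates with the truth at r ≈ 0.9, with
root-mean-square proportion errors below 0.1 and Jensen–Shannon
divergences far below the uniform-guess baseline (≈ 0.16).

```r
# domains on a 3-slice stack with a batch effect, then rigid alignment
stack <- generate_stack3d(n_slices = 3, spots_per_slice = 300, n_domains = 3,
                          batch_shift = 0.3, seed = 4)
dom <- spatial_domains(stack, n_domains = 3, seed = 5)
domain_metrics(dom$domains, unlist(lapply(stack, `[[`, "domains")))$ari
#> [1] 0.9635844

for (j in seq_along(stack))
  stack[[j]]$domains <- dom$domains[dom$slice_of_spot == j]
pert <- perturb_stack(stack, crop_ratio = 0.1, seed = 6)   # random flip/rotate/shift/crop
aligned <- align_stack(pert$slices, z_spacing = 10, seed = 7)
aligned
#> <aligned_stack> 3 aligned slices, z spacing 10 um
#>   slice01: theta =  0.000, flip = +1, t = (    0.0,     0.0)
#>   slice02: theta =  0.025, flip = +1, t = (  -50.7,  -193.6), AOF = 0.896
#>   slice03: theta =  0.996, flip = -1, t = ( -141.8,  -128.3), AOF = 0.890

# continuous 3D expression of a smooth gene and its spatial Bayes factor
xyz <- stack_coords3d(aligned)
y <- 0.02 * xyz[, 3] + 5e-4 * xyz[, 1] + rnorm(nrow(xyz), 0, 0.05)
gp <- fit_gpr(xyz, y)
bayes_factor(gp)$log_bf
#> [1] 1283.891
```

The domain labels recover the planted domains (adjusted Rand index 0.96)
despite the slice-level batch shift; the alignment recovers each slice's
random flip/rotation/translation (per-pair AOF ≈ 0.89, near its upper
bound of 1 given domain-boundary mixing); and the planted smooth gradient
gets an overwhelming spatial Bayes factor, where white noise would give
log BF ≈ 0.

A command-line interface wrapping the same functions is installed as
`exec/spstack` (subcommands `simulate`, `deconvolute`, `domains`, `align`,
`gpr`, `evaluate`).

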