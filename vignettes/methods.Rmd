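---
title: "Models and methods in spstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in spstack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

spstack analyses multi-slice spatial transcriptomics in four stages —
spot deconvolution, joint spatial-domain identification, rigid 3D
reconstruction, and continuous 3D expression modelling — plus the
simulation and evaluation machinery needed to test each stage on data with
known ground truth. This vignette explains each model, its assumptions, the
parameters that matter, and the numerical choices the implementation makes.
All coordinates are metric micrometres in a planar Cartesian frame; no
pixel or array-index convention appears anywhere, because the alignment
mathematics (neighbour distances, translation bounds, shifting distances)
is metric.

## Spot deconvolution (`deconvolute()`)

Sequencing-based spatial platforms capture mRNA from several cells per
spot. `deconvolute()` estimates each spot's cell-type proportions by training on
*pseudo-spots*: synthetic mixtures assembled from a single-cell reference,
where the composition is known because the constituent cells are known.

**Pseudo-spot construction** (`simulate_pseudospots()`). For each
pseudo-spot the number of cells $N_c$ and number of types $N_t$ are drawn
from normal distributions with defaults $\mu_c = 10$, $\delta_c = 5$,
$\mu_t = \mu_c/2$, $\delta_t = \delta_c/2$ — about ten cells per spot, the
regime of a 55-µm capture spot. Draws are rounded and clamped to
$N_c \ge 1$, $1 \le N_t \le \min(N_c, \text{n types})$; clamping rather
than redrawing keeps the generator deterministic under a seed. A per-spot
uniform draw $r_c$ selects how types are sampled: by their reference
frequencies $f_t$ ($r_c < 1/3$), by normalized reciprocals $1/f_t$
(middle third, over-sampling rare types so the training set covers them),
or by normalized $\sqrt{f_t}$ (final third, a compromise). Types with
$f_t = 0$ are excluded before the reciprocal is formed. $N_t$ types are
drawn by this law, the law is renormalized over the chosen subset, and
$N_c$ cells are sampled *with replacement* (small references must not be
exhausted). Their counts are summed and the sampled type counts divided by
$N_c$ are the exact ground-truth proportions. Finally each pseudo-spot is
thinned to a sequencing depth drawn from $N(\mu^L, \sigma^L)$ estimated
from the real slice, using exact multivariate-hypergeometric sampling
(`downsample_counts()`): totals hit the target exactly, no count increases,
and expected gene proportions are preserved.

**Architecture.** Three networks share the work. A variational autoencoder
(hidden widths 128–64–128, Gaussian latent prior, mean-squared
reconstruction of library-size + log1p normalized expression) embeds
simulated and real spots in one 64-dimensional latent space; it is
pretrained on the union of both sets, and the deterministic encoder mean is
used downstream. A predictor MLP (three 512-unit ReLU layers, softmax
output) maps latents to proportions. A recovery MLP of the same shape maps
predicted proportions back toward the latent, so that proportions cannot
discard the expression information. The squared maximum mean discrepancy
(Gaussian kernel, bandwidth equal to the hidden width) between simulated
and real embeddings of the predictor's last hidden layer aligns the two
distributions, protecting against the domain gap between pseudo-spots and
real spots.

**Losses.** The proportion loss is
$(1 - \cos(\hat p, p)) + \mathrm{KL}(p \,\|\, \hat p)$ averaged over
spots, which is non-negative and zero exactly at equality; both KL
arguments are floored at $10^{-8}$ (natural log). The KL gradient keeps the
floored-denominator form $-p/\max(\hat p, \varepsilon)$: through the
softmax this bounds the pull at $-p$ and lets saturated outputs recover —
zeroing the gradient below the floor would trap a collapsed class
permanently. The recovery loss is $(1 - \cos) + \mathrm{MSE}$ between the
recovered vector and the latent; a KL term is not meaningful there because
latents are unconstrained reals, so the package uses the mean-squared
error as the magnitude-matching term.

**Training.** He-initialized weights; per epoch, (1) an Adam step on the
predictor against the proportion loss over simulated spots, then (2) a
joint Adam step on predictor and recovery head against recovery loss plus
MMD over all spots. Training stops when the proportion loss changes by
less than `conv_tol` ($10^{-3}$) for `conv_patience` (5) consecutive
epochs — a single small step on a transient plateau is not convergence.
The optimization settings are deliberate: full-batch Adam at learning rate
$10^{-3}$ with global gradient-norm clipping at 5 for the heads, and
$3\times10^{-3}$ / clip 10 / KL weight $10^{-4}$ / 1200 epochs for the
VAE. At smaller learning rates the model is far from converged within any
reasonable epoch budget, and without clipping the 512-unit layers
intermittently collapse one class; clipping plus a larger step is the
standard remedy and keeps every run bit-reproducible under the seed. The
model gene space is the union of the top `n_markers_per_type` reference
markers per type (vectorized rank-sum ranking) intersected with the
slice's genes.

## Joint spatial-domain identification (`spatial_domains()`)

Spatial domains are regions coherent in both composition and position.
The input is the spot-by-type composition matrix of each slice (from
`deconvolute()` or any other source); working on compositions rather than
expression makes slices from different batches directly comparable.

Each slice gets a k-nearest-neighbour graph (`build_graph()`, default
$k = 6$, the hexagonal neighbourhood of a Visium spot; ~25 is appropriate
for single-cell-resolution platforms), symmetrized, with normalized
Laplacian $L = I - D^{-1/2} A D^{-1/2}$ and scaled form
$\tilde L = 2L/\lambda_{\max} - I$ whose spectrum lies in $[-1, 1]$.
$\lambda_{\max}$ comes from power iteration stopped on the residual
$\|Lv - \lambda v\|$, which is a rigorous error bound for symmetric
matrices; the residual is added to the estimate so the scaled spectrum
cannot overshoot. Convolutions are Chebyshev polynomial filters
(`cheb_filter()`): $y = \sum_{k=0}^{K-1} T_k(\tilde L)\, X\, \theta_k$
with the recurrence $\bar x_k = 2\tilde L \bar x_{k-1} - \bar x_{k-2}$;
$K = 2$ (default) mixes first- and second-order neighbourhoods. Graphs of
different slices are processed as separate blocks — no cross-slice edges;
correspondence between slices is the alignment stage's job.

The network has five layers (composition → 64 → 16 → 64 → composition,
Xavier-initialized): a cosine reconstruction loss ties the softmax output
layer to the input composition; a smoothness loss penalizes the mean
absolute difference between each spot's 16-dimensional latent and the
average latent of its graph neighbours; and a discriminator
(16 → 64 → 64 → n-slices) tries to classify which slice each latent came
from. Training is standard two-player adversarial optimization with
RMSProp: the discriminator minimizes its cross-entropy (several steps per
epoch, default 3, keeping it near its optimum so its gradient on the
network is informative), and the network minimizes
$\alpha_C L_C + \alpha_S L_S - \alpha_D L_D$ (defaults 1, 1, 0.5) — the
minus sign makes the network *maximize* the discriminator's loss, pushing
the slices' latent distributions together. With a single slice the
adversarial branch is disabled automatically. Every epoch, K-means on the
pooled latent is scored with the Davies–Bouldin index; training stops when
the total loss change falls below $10^{-4}$ *and* the index has stopped
improving within a 10-epoch patience window. Final domains are K-means
clusters (10 restarts, labels relabelled by decreasing cluster size for
stability) on the pooled latent, one label vocabulary across all slices.

## Rigid 3D reconstruction (`align_stack()`)

Consecutive sections of one tissue block are arbitrarily rotated, shifted
and sometimes mirrored on their slides. `align_stack()` centres every
slice at the origin, keeps the first fixed, and aligns each slice to the
already-transformed previous one with a rigid transform
$S' = R\,M\,S + T$ — rotation $\theta$, mirror
$M = \mathrm{diag}(\mathrm{flip}, 1)$, translation $(dx, dy)$.

The alignment objective (`aof()`) scores a candidate placement by domain
agreement: mutual k-nearest-neighbour pairs (default $k = 10$) between the
transformed source and the target are formed, pairs farther than a
distance cut-off are dropped (default: median distance of target spots to
their $2k$-th neighbour within the target slice), a source spot is
*overlapped* when at least one mutual neighbour survives, and the score is
the mean fraction of surviving neighbours sharing the source spot's
domain, plus the penalty $-|n_o/n_j - 1|^p$ on the non-overlapping
fraction (default $p = 2$; the absolute value keeps the penalty a penalty
for every exponent). The objective is bounded by 1 and reaches it exactly
when all spots overlap and every mutual neighbour agrees — note that
interior domain boundaries dilute the agreement term even at perfect
alignment, so the bound is attained only on domain-pure neighbourhoods.

Optimization is differential evolution (rand/1/bin, population 30, 60
generations by default) over $(\theta, dx, dy)$, run separately for
flip $= \pm 1$ with the better optimum kept, so the continuous search
stays continuous. Translation bounds are the sum of the two slices'
bounding-box half-diagonals, which makes any overlap reachable. The
mutual-neighbour structure is recomputed from the candidate coordinates at
every evaluation; that inner kernel is the one piece of compiled code in
the package. The search is stochastic but fully seeded.

## Continuous 3D expression and spatial variability (`fit_gpr()`)

After alignment, expression of one gene over the stacked coordinates is
modelled as a constant-mean Gaussian process with squared-exponential
covariance $\delta^2 \exp(-|x - x'|^2 / 2\ell^2)$ plus Gaussian noise, on
log-normalized values (the Gaussian likelihood is reasonable on that
scale). Initialization follows a grid search: $\mu = \bar y$,
$\delta = 4$, and $\ell = \lambda \,\mathrm{var}(y)$ with $\lambda$ chosen
from $\{10^{-2}, \dots, 10^{4}\}$ by marginal likelihood. The grid spans
five decades deliberately: for variances of order one the candidate length
scales must reach from micrometres to centimetres, because the marginal
likelihood is flat in $\ell$ far below the spot spacing and a refinement
started there has no gradient signal. All hyperparameters (mean, process
variance, length scale, noise variance) are then refined by Adam ascent on
the exact log marginal likelihood with analytic gradients; with no prior
specified the maximum-a-posteriori estimate coincides with the maximum
likelihood. Non-positive-definite kernels get jitter escalation
($10^{-8}$ to $10^{-4}$ of the mean diagonal) before failing.

Spatial variability is a Bayes factor (`bayes_factor()`): the likelihood
ratio of the fitted spatial model against the $\ell \to \infty$ limit, in
which the covariance is the constant $\delta^2$ — algebraically a shared
random offset plus noise, with no spatial structure. The limit is used
analytically; no numerical infinity appears. The null's remaining
hyperparameters are re-optimized, and its $\delta \to 0$ closure (iid
Gaussian noise) has a closed-form optimum that is also evaluated, with the
better of the two taken — the comparison must not be biased by an
under-optimized null. Ratios are computed in log space. For constant input
the two models coincide and the factor is defined as 1. Since both models
are optimized by maximum likelihood and the spatial model has one extra
hyperparameter, white-noise input yields factors slightly above 1 on
occasion; the calibration check asserts a median at or below 1.2 over 20
replicates, the overfitting margin expected from one extra parameter.

For visualization and surface statistics, `build_mesh()` computes a 3D
Delaunay tetrahedralization (incremental Bowyer–Watson over
deterministically micro-jittered points; the jitter breaks the cospherical
degeneracies of grid-arranged spots), keeps tetrahedra with circumradius
below `alpha` (the convex hull in the large-`alpha` limit), extracts
boundary triangles, and smooths with Loop subdivision (each round
quadruples the face count). `sample_mesh()` draws area-weighted uniform
surface points; the production-scale budget of 500,000 points is a knob —
predictions are pointwise, so any budget gives the same values at shared
points, and the tests use $10^3$–$10^4$.

## The synthetic-data generators, and what passing means

`generate_reference()` draws negative-binomial counts with lognormal
baseline means shared across types; each type over-expresses a disjoint
marker block by `marker_logfc` (log2). This emulates the marker structure
of a curated scRNA-seq reference but not its full complexity: no nuisance
covariates, no ambient contamination, no continuum between types.

`generate_stack3d()` emulates serial sections: jittered-grid spots in a
1400 × 1700 µm rectangle, domains that are spatially contiguous and drift
smoothly with depth, per-domain composition profiles perturbed in logit
space, and an optional slice-level logit shift as a batch effect. The
laminae are gently curved (a sine in x) — real cortical layers are curved,
and perfectly straight bands would be an unrealistic symmetry that leaves
a slice's placement underdetermined along the band direction. The
domain-identification fixture uses 3 domains; the alignment fixture uses 5,
emulating a layered cortical sample. `perturb_stack()` applies the
sectioning-damage protocol: every slice but the first is randomly
mirrored, rotated uniformly in $[0°, 360°)$, translated 300–2000 µm per
axis with random sign, and cropped from its edge by removing the
`crop_ratio` fraction of spots with the largest projection onto a random
direction; true transforms and retained indices are recorded, so the
perturbation is exactly invertible on retained spots.

Passing on these fixtures shows that each stage recovers what it is
designed to recover under controlled, favourable conditions — clean marker
structure, correct reference, modest noise. It does not demonstrate
robustness to reference mismatch, platform-specific noise, segmentation
errors, or deformable tissue distortion.

## Problem sizes and reproducibility

The test and acceptance runs use deliberately scaled-down problems chosen
as the smallest sizes at which each recovery is stable: deconvolution
trains on 1,000 pseudo-spots against a 500-cell, 5-type reference and
evaluates on 500 held-out pseudo-spots; domain identification uses 3
slices of 300 spots; alignment uses 10 slices of 200 spots at crop ratios
0, 0.1 and 0.25; the Gaussian-process calibration uses 200 points and 20
null replicates. One user-facing seed drives every stage; each stage
derives its own sub-seed from it with fixed offsets, so stages are
independently reproducible and every run is bit-identical on one platform.

## Known limitations

Alignment is rigid only — no deformable registration, and no global
refinement after sequential pairwise chaining, so errors can accumulate
along very long stacks. Domain identification consumes compositions, not
expression, so a deconvolution (or cell typing) step must precede it on
spot-level data. The Gaussian-process stage fits one gene at a time with
dense Cholesky factorizations, practical to a few thousand points per
gene. Adding a new slice requires retraining the domain model from
scratch.
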