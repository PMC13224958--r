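---
title: "The scwarp model: shared reference axes with sample-specific distortions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scwarp model: shared reference axes with sample-specific distortions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The generative model

`scwarp` models multi-sample single-cell expression as observations of one
shared low-dimensional manifold that every sample warps slightly. For cell
$n$ belonging to sample $i$, the normalized expression vector
$y_n \in \mathbb{R}^G$ is

$$ y_n = o + s_n \mathbf{1} + (Z + \Delta Z_i)\, b_n + \varepsilon_n,
   \qquad \varepsilon_n \sim \mathcal{N}(0, \sigma^2 I), $$

with

* $Z$ (genes × $K$): orthonormal **reference axes** spanning the shared
  biological manifold;
* $\Delta Z_i$ (genes × $K$): the **sample distortion**, an additive warp
  of the axes capturing batch- or condition-specific deformation;
* $b_n \in \mathbb{R}^K$: the cell's coordinates in the shared latent
  space;
* $o$ (genes): gene offsets (baseline log expression);
* $s_n$ (scalar): the cell's size factor, additive in log space.

Raw counts are transformed as $\log(1 + 10^4\, x/\mathrm{colsum})$ before
fitting; pre-normalized input is used verbatim (flagged on the dataset).

Three quantities of scientific interest fall directly out of the fitted
decomposition: $Z b_n$ is batch-corrected expression; $\Delta Z_i b_n$ is
the expression distortion sample $i$ imposes on cell $n$; and $B^\top$ is
the integrated embedding (input to neighborhood graphs / UMAP, which this
package deliberately does not compute).

Two optional priors extend the model. A **sample design** $X$ (samples ×
covariates) links distortions to sample-level variables through a linear
map $D$, $\Delta Z_i \approx D(x_i)$; the covariate slice $D_t$ then
yields the clustering-free **differential-expression vector field**
$D_t b_n$ — the per-unit-covariate change in expected expression at cell
state $b_n$ — summarized per gene by the root-mean-square shift across
cells (a deliberate choice: magnitude-faithful, cluster-free, and no
significance calibration is attached because none is modeled). A
**gene-program prior** $A$ (genes × programs, optionally signed regulons
from GMT files) constrains the axes to program combinations, $Z = A W$,
so that $W b_n$ projects per-cell program activities.

## Objective and penalties

Fitting minimizes the penalized least squares objective

$$ \mathcal{L} = \sum_n \lVert y_n - o - s_n\mathbf{1} - (Z+\Delta Z_i) b_n \rVert^2
  + \lambda_b' \sum_n \lVert b_n \rVert^2
  + \lambda_\delta' \sum_i \lVert \Delta Z_i - D(x_i) \rVert_F^2
  + \lambda_d' \lVert D \rVert_F^2
  + \lambda_w' \lVert W \rVert_F^2 . $$

The penalties are Gaussian priors in a MAP reading of the model, so their
natural units are the noise variance: the effective weights are
$\lambda' = \lambda \,\hat\sigma_0^2$, where $\hat\sigma_0^2$ is the
mean squared residual of the rank-$K$ initialization, estimated once and
then fixed (so the optimized objective is a fixed quadratic). This makes
the defaults $\lambda_b = \lambda_\delta = \lambda_d = \lambda_w = 1$
genuinely mild at any data scale. A unit penalty applied to the raw
sum-of-squares instead would shrink every embedding by
$1/(1+\lambda_b) = 50\%$ regardless of how clean the data are — a
scale-dependent distortion with no statistical motivation. With no design
supplied, $D \equiv 0$ and the distortions are shrunk toward zero; the
plain-integration and DE-enabled models are the same code path.

## Identifiability: the gauge

A factorization $(Z + \Delta Z_i) b_n$ has continuous symmetries that must
be fixed before "the" parameters are meaningful. `scwarp` works in the
following gauge, enforced after every iteration:

1. $Z^\top Z = I_K$, with each axis's largest-magnitude loading positive
   (ties broken toward the lowest gene index) — removes rotation, scale
   and sign freedom;
2. rows of $B$ have zero mean across cells, the means being absorbed into
   $o$ — separates offsets from factors;
3. $Z^\top \Delta Z_i = 0$ — distortions carry only expression structure
   orthogonal to the reference axes.

The third condition deserves comment. Without it, the split between
$Z b_n$ and $\Delta Z_i b_n$ is degenerate: a multiple of $Z$ can migrate
into **every** sample's distortion while the embeddings rescale, leaving
reconstructions identical. Worse, with a ridge on $B$ this degenerate
valley tilts — the optimizer can always trade embedding norm against a
shared distortion inflation — so "batch-corrected expression" would be an
arbitrary fraction of the signal. Constraining distortions orthogonal to
the axes removes the overlap: what is shared lives in $Z$, what is
sample-specific lives in $\Delta Z_i$. The constrained distortion update
stays closed-form because the ridge Gram acts on the right of the
solution, so projecting the unconstrained solution is the exact
constrained minimizer. Note the dual consequence: only the
$Z$-orthogonal component of a sample's true warp is attributed to
$\Delta Z_i$; any component along the axes is indistinguishable from a
per-sample re-weighting of shared factors and is not claimed.

Analogously, the scalar size factor absorbs the all-ones gene direction,
so reference axes are only identified orthogonal to $\mathbf{1}$; and the
cell-weighted mean distortion is part of the shared manifold, so
distortions are only identified up to their mean across samples.

## Initialization

Model setup allocates every parameter block at its final shape (nothing
is reshaped later). Initialization then sets $o$ to per-gene means, $s$
to per-cell means of the gene-centered data, and $(Z, B)$ to a seeded
randomized truncated SVD of the doubly centered matrix (4 power
iterations, oversampling 10) — the global optimum of the distortion-free,
penalty-free subproblem. All products with the centered matrix are formed
blockwise per sample, so the sparse input is never densified. The rank-$K$
residual of this SVD provides $\hat\sigma_0^2$. Embeddings are then
ridge-shrunk by $1/(1+\lambda_b \hat\sigma_0^2)$ (the exact penalized
minimizer given orthonormal axes), and the gauge is applied. An exactly
zero centered matrix falls back to canonical basis axes with a warning.

## Block-coordinate descent

Each iteration applies, in order: cell embeddings → sample distortions →
covariate map → reference axes → re-orthogonalization → offsets. Every
step is the exact minimizer of the objective over its block (subject to
the gauge), so the recorded loss trajectory is non-increasing — a property
the test suite asserts at $10^{-9}$ relative tolerance.

* **Embeddings**: per sample, with $M_i = Z + \Delta Z_i$,
  $b_n = (M_i^\top M_i + \lambda_b' I)^{-1} M_i^\top (y_n - o - s_n\mathbf{1})$,
  the Gram formed once per sample.
* **Distortions**: per sample,
  $\Delta Z_i = (R_i B_i^\top + \lambda_\delta' D(x_i))(B_i B_i^\top + \lambda_\delta' I)^{-1}$
  followed by projection off $\mathrm{span}(Z)$; a cell-less sample
  receives its projected prior mean.
* **Covariate map**: one ridge regression of the vectorized distortions
  on $X$ with ridge $\lambda_d/\lambda_\delta$ (a global, synchronized
  step).
* **Reference axes** (no prior): the exact minimizer over $Z$ under the
  orthonormality constraint with $B$ fixed is the orthogonal-Procrustes
  solution — the polar factor $UV^\top$ of the cross-moment
  $C_{yb} = \sum_n (y_n - o - s_n\mathbf{1} - \Delta Z_i b_n) b_n^\top$.
  An unconstrained regression solve followed by QR with the scale pushed
  into $B$ is *not* used here: that composite map has no fixed point once
  $\lambda_b > 0$ (the ridge shrinks $B$, the regression re-inflates $Z$,
  and QR pushes the scale back into $B$), and its loss oscillates. The
  Procrustes step is scale-free, monotone at any penalty weight, and in
  the single-sample penalty-free limit reproduces orthogonal iteration,
  i.e. the truncated SVD.
* **Reference axes** (with prior): the unconstrained solve
  $Z^* = C_{yb} C_{bb}^{-1}$ is projected onto program space,
  $W = (A^\top A + \lambda_w' I)^{-1} A^\top Z^*$, $Z^* \leftarrow AW$,
  followed by thin QR re-orthogonalization with $B \leftarrow RB$ and
  $W \leftarrow W R^{-1}$, preserving both $Z = AW$ and the reconstruction.
* **Offsets**: $o$ and $s$ are sequential exact mean-residual updates,
  then the embedding row means are re-absorbed into $o$.

Convergence is declared when the relative loss change drops below `tol`
(default $10^{-6}$; default `max_iter` 100). On the reference fixture the
fit converges in 3–4 iterations.

### Parallel and storage contracts

Per-sample updates are mathematically independent; `n_workers > 1` maps
them onto forked processes. Global steps reduce per-sample partial sums in
ascending sample index *regardless* of worker count or processing order,
so fits are bit-identical across `n_workers` and any `sample_order`
permutation — the suite asserts equality at $10^{-10}$ and observes 0.
Expression values enter dense arithmetic only through per-sample dense
scratch blocks (genes × cells-in-sample); sparse and densified inputs
therefore follow identical floating-point paths, and no operation after
setup materializes a dense genes × all-cells array. An allocation-tracking
hook (`options(scwarp.track_alloc = TRUE)`) records every dense scratch
allocation so tests can assert the contract rather than trust it.

## The synthetic-data generator

`generate_dataset()` emulates exactly the structure the model assumes, so
every stage is testable against known truth without downloads. Latent
states are a mixture of 3 clusters (per-coordinate center sd 2) plus a
one-dimensional trajectory (direction uniform on the sphere, position
Uniform(0, 2)) plus within-cluster spread sd 1, then centered and
whitened to covariance $4 I_K$. Whitening is the load-bearing choice:
with 3 centers the between-cluster spread is rank 2, so at some seeds the
raw latent covariance has a small eigenvalue whose axis would be
indistinguishable from the distortion background — no method could
recover it. Axes are defined only up to rotation, so stating the truth in
the whitened basis loses no generality, and it guarantees every axis the
same variance. The truth is generated directly in the model's gauge:
orthonormal $Z_{\mathrm{true}}$ orthogonal to $\mathbf{1}$, centered
$B_{\mathrm{true}}$, distortions orthogonal to the axes and averaging to
zero across samples.

Distortions are $\Delta Z_i = (x_i - \bar x) D + \texttt{distortion\_scale}
\cdot E_i$ with $E_i$ Gaussian at the same per-entry scale as the axes
($1/\sqrt{G}$) and mean-removed across samples; the binary `disease`
covariate splits samples evenly, and its effect is symmetric
($\pm D/2$, contrast $D$). The design handed back includes an intercept
column so the fitted covariate map separates shared from differential
distortion. The planted slice $D$ is supported on `n_de_genes` genes with
entries of sd $\texttt{covariate\_effect}/\sqrt{G}$ — effect 1.0 means "a
distortion comparable to a typical axis loading" on those genes. Gene
offsets are $\mathcal{N}(0,1)$, size factors $\mathcal{N}(0, 0.2^2)$,
measurement noise i.i.d. Gaussian (default sd 0.1). With a program prior,
signed disjoint gene blocks form $A$, $Z_{\mathrm{true}} = A W$
re-gauged, and true activities $W_{\mathrm{true}} B_{\mathrm{true}}$ are
recorded. `generate_counts()` pushes the Gaussian means through `exp`,
renormalizes per cell and draws Poisson counts at a target depth, so the
count-normalization path is exercised end to end.

What the generator deliberately does **not** emulate: dropout mixtures,
doublets, ambient RNA, overdispersed counts, or nonlinear manifold
geometry. Passing tests therefore demonstrate correctness of the
estimator under its own assumptions — identifiability, convergence,
invariances, recovery at realistic SNR — not robustness to every artifact
of real scRNA-seq data.

## Numerical choices

* Convergence: relative loss change, default `tol = 1e-6`, `max_iter = 100`.
* Near-singular systems: ridge-free solves fall back to a pseudo-inverse
  with a warning; a rank-deficient embedding cross-moment receives an
  $\varepsilon$-ridge of $10^{-10}\,\mathrm{trace}$; rank-deficient
  reference axes are an error naming the collapsed factor.
* Sign/tie rule: the largest-magnitude loading per axis is made positive,
  ties to the lowest gene index, making runs bitwise reproducible.
* The model archive stores arrays as C99 hex-float text, which round-trips
  IEEE doubles bitwise through `strtod`; the MatrixMarket writer prints 17
  significant digits for the same reason.
* The loss trajectory's first entry is the objective of the allocated
  zero model (the sum of squared data) — the natural baseline for
  "final/initial" loss ratios, since the SVD initialization itself already
  attains near-zero loss on clean data.

## Problem sizes used by the test suite

Unit tests run on instances between 6 × 8 and 120 × 600; the acceptance
tests and `scripts/acceptance.R` use the reference fixture (200 genes,
$K = 5$, 4 samples, 2000 cells) plus a 200 × 2000 single-sample variant
for the SVD-limit check, sizes at which every property is measurable in
seconds on one core.

## Known limitations

* The Gaussian least-squares objective is a choice; count-native
  likelihoods (Poisson/NB) are not implemented, only count *input* via
  the log1p normalization path.
* With a gene-program prior the reference update is a projection of the
  unconstrained solve, not the exact constrained minimizer, and the QR
  re-gauge can in principle wobble the penalized loss at the last decimal
  places; in practice trajectories on the test fixtures remain strictly
  decreasing.
* Distortion components parallel to the reference axes are not
  identifiable and are deliberately not claimed (see the gauge section).
* No statistical significance is attached to vector-field gene scores;
  they are effect-size rankings.
* Alternative-splicing (dual-measurement) modalities and
  UMAP/clustering/annotation are out of scope.
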