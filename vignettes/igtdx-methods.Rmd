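---
title: "Pseudo-image conversion of feature tables: models, metrics and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-image conversion of feature tables: models, metrics and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Convolutional networks expect spatially structured input, while omics and
other tabular datasets are unordered collections of feature columns.  The
IGTD (Image Generator for Tabular Data) family of methods bridges the gap
by *assigning each feature to a pixel* of an $N_r \times N_c$ grid (with
$N_r N_c = p$) so that features that are close in the data are close on
the grid, then rendering each sample's feature vector as a grayscale
pseudo-image.  `igtdx` implements this conversion with six feature
dissimilarities, the matching suite of simulation generators, and a small
CNN cross-validation harness to score how classifiable the resulting
images are.

## The layout objective

Let $D$ be the $p \times p$ matrix of pairwise feature dissimilarities and
let the pixel distances on the grid be Euclidean distances between integer
pixel coordinates.  Both sets of $p(p-1)/2$ pairwise values are ranked
ascending into integer rank matrices $R$ (features) and $Q$ (pixels), and
the quality of an assignment is

$$\mathrm{err}(R', Q) = \sum_{i>j}\left(r_{ij} - q_{ij}\right)^2,$$

where $R'$ is $R$ with rows and columns permuted synchronously by the
feature-to-pixel assignment.  Working with ranks rather than raw distances
makes the objective invariant to any monotone rescaling of the metric —
which is what lets non-Euclidean dissimilarities drive a Euclidean pixel
grid.

**Ranking ties.**  Ranks are ordinal (`ties.method = "first"`) over the
pair scan order $(2,1), (3,1), (3,2), (4,1), \ldots$.  Each rank in
$1..p(p-1)/2$ is therefore used exactly once, `err` is integer-valued, and
the whole pipeline is deterministic.  Any fixed tie rule is equally
defensible; we document ours so results are exactly reproducible.

**Swap search.**  `optimize_layout()` iterates: pick the grid position
with the largest error contribution among positions not picked within the
last `cooldown` iterations (default $\lfloor p/2 \rfloor$ — the cooldown
stops the search from hammering the same high-error position), score a
swap against every other position with an $O(p)$ incremental update, and
accept the best strictly improving swap (ties to the smallest partner
index).  The incremental update is exact, which the test suite verifies
against full recomputation.  Termination: `max_steps` iterations (default
3000) or `stall_limit` consecutive non-improving iterations (default 200).
The error trace is strictly decreasing over accepted swaps and is stored
in the layout so users can verify the plateau.  The search is greedy and
carries no randomness: given $(R, Q)$ and the settings it always returns
the same permutation.

**Intensity scaling.**  Each feature is min-max scaled to $[0,1]$ over the
samples; constant features map to 0.5.  Per-feature scaling preserves each
feature's relative variation regardless of its units; the scaling
parameters are stored with the layout, so images invert exactly back to
the data (`test-acceptance` checks the round trip at $10^{-9}$).
Grids that do not satisfy $N_r N_c = p$ are an error — no silent padding.

## The six feature dissimilarities

All metrics compare feature *columns*; the pixel grid always stays
Euclidean.

* **ED** — Euclidean distance between columns.  Appropriate when features
  are commensurate and relationships are linear.
* **RD** — $1 - \rho$ (Pearson).  Range $[0,2]$; scale-invariant; captures
  only linear dependence and is not a true metric (no triangle
  inequality).  Zero-variance columns have undefined $\rho$; we assign
  distance 1 (the uncorrelated value) with a warning so degenerate
  simulated columns stay finite.
* **GD** — geodesic distance: build a symmetric $k$-nearest-neighbour
  graph over features ($k = 10$ by default; an edge is kept when either
  endpoint lists the other), weight edges by Euclidean distance, and take
  all-pairs shortest paths (Dijkstra on the sparse graph — identical by
  definition to the dense $O(p^3)$ recurrence, but feasible at large
  $p$).  If the graph is disconnected (the "pinch problem"), components
  are merged by repeatedly adding the single minimum-Euclidean-distance
  inter-component edge (single linkage).  GD dominates ED entrywise, with
  equality whenever the direct edge exists.
* **JD** — Jensen-Shannon divergence between per-feature probability mass
  functions over the samples: columns are normalised to sum to one (or
  passed through a per-column softmax when the data contain negative
  values, e.g. z-scores; all-zero nonnegative columns fall back to a
  uniform PMF with a warning), and
  $\mathrm{JS}(P_i, P_j) = \tfrac12 KL(P_i \| M) + \tfrac12 KL(P_j \| M)$
  with $M$ the midpoint mixture and base-2 logarithms, so values lie in
  $[0,1]$.  $0 \log 0$ terms contribute zero.  Note that only the *square
  root* of this quantity is a true metric; the divergence itself is the
  default because its $[0,1]$ range is the conventional reporting scale,
  and a `sqrt_divergence` flag provides the metric form.  Since ranks are
  monotone in the value, the layout is identical either way.
* **WD** — 1-D Wasserstein distance in quantile form: for each pair of
  columns, $\sqrt{\tfrac1n \sum_k (x_{(k)i} - x_{(k)j})^2}$ over order
  statistics.  This discretises $\int_0^1 |F_i^{-1} - F_j^{-1}|^2$ at the
  $n$ empirical quantiles, so a constant shift $c$ of a column moves the
  distance by exactly $|c|$ and within-column order is irrelevant.  The
  package also exposes the Gaussian closed form
  $(\mu_X-\mu_Y)^2 + (\sigma_X-\sigma_Y)^2 + 2\sigma_X\sigma_Y(1-\rho_{XY})$,
  used as a large-sample oracle with $\rho_{XY}=1$ (the comonotone
  coupling implied by sorting).  The $2\sigma_X\sigma_Y(1-\rho_{XY})$ term
  makes this a *joint*-Gaussian quantity rather than the marginal W2; it
  is implemented as stated and used only at $\rho_{XY}=1$, where the two
  coincide.
* **TD** — tropical (max-plus) distance
  $\max_k(x_{ki}-x_{kj}) - \min_k(x_{ki}-x_{kj})$: the range of
  coordinate-wise differences.  Invariant to adding a constant to either
  column, hence sensitive to dominance patterns rather than levels.

## The simulation generators

Each generator plants its signal in the first `p_signal` (default 100)
columns and pads with label-independent Gaussian noise to `p` columns
(default 2500, i.e. a 24:1 noise-to-signal ratio).  With `n = 200`
(default) the six models emulate the study conditions the package is
designed to reproduce.  All draws run through R's RNG under a single
`set.seed(seed)`, so datasets are exactly reproducible.

* **euclidean** — signal $\sim N(0, 2I)$, coefficients
  $\beta \sim N(2.5\mathbf{1}, I)$ drawn once per dataset,
  $\mathrm{logit}\,P(Y{=}1) = X\beta$, labels Bernoulli.  (The variance-2
  signal follows the model's defining formula.)  By design *no* metric has
  a geometric advantage here; all methods hover near chance under heavy
  noise, making this a baseline rather than a contrast.
* **correlation** — signal $\sim N(0, \Sigma)$ with Toeplitz
  $\Sigma_{jk} = 0.95^{|j-k|}$, coefficients the fixed grid
  $(0.01, 0.02, \ldots, 1)$, logits scaled by 3.
* **geodesic** — points on a Swiss roll
  $(t\cos t,\; h,\; t\sin t)$ with $t \sim U[1.5\pi, 4.5\pi]$,
  $h \sim U[0, 21]$, zero-padded to `p_signal` dimensions and rotated by a
  seeded random orthogonal matrix (QR of a Gaussian matrix) — an isometric
  embedding, so norms are preserved.  The model description leaves the
  labelling function open; we use the graph-geodesic distance from the
  first sample along the symmetric $k=10$ sample graph and split at the
  median (ties to class 0), which yields exactly balanced classes and a
  boundary that follows the manifold rather than any linear direction.
  Reference point, $k$ and the embedding are configurable.
* **js** — labels Bernoulli(0.5); signal rows are symmetric Dirichlet
  compositions, concentration 0.1 for class 0 (spiky) and 5 for class 1
  (even).  Both classes share the coordinate mean $1/p_{\text{signal}}$;
  the classes differ purely in distributional shape.
* **wasserstein** — each signal row is the sorted vector of
  `p_signal` draws from $N(Y', 1)$ with generating label
  $Y' \sim$ Bernoulli(0.5); the template $T$ is the mean class-0 quantile
  vector, $W_1(x, T) = \sum_j |\sum_{k \le j} (x_k - T_k)|$ (cumulative-sum
  form), and the *final* label is the above-median indicator of $W_1$
  (ties to class 0; exactly balanced).  Both $Y'$ and $Y$ are kept in the
  dataset metadata; only $Y$ is the exposed label.
* **tropical** — signal indices are shuffled and cut into $S = 5$
  near-equal segments; per sample and segment a plateau level
  $\sim U(-1,1)$; two segments $s^+ \ne s^-$ chosen once per dataset are
  shifted $+\Delta$ / $-\Delta$ for class-1 samples
  ($\Delta = 1.75$, the midpoint of the design range $[1.5, 2]$); within-
  segment jitter $N(0, 0.1^2)$; columns are centred by default, which
  suppresses the mean cues Euclidean/correlation metrics would exploit
  while leaving the tropical distance untouched; the noise block uses
  $\sigma = 0.01$.

What the generators deliberately *do not* emulate: real omics data are
heteroskedastic, batch-affected and correlated between "noise" features;
the generators' noise is i.i.d. Gaussian.  Passing the reproduction
checks therefore demonstrates that the conversion and evaluation pipeline
behaves as designed under each model's stated geometry — not that any
particular metric will win on a given real dataset.

## The CNN evaluation protocol

The reference classifier is intentionally small and fixed: two blocks of
(3×3 convolution, stride 1, same padding → batch normalisation → ReLU →
2×2 max-pool), a 64-unit dense layer with ReLU and dropout 0.25, and a
sigmoid output trained with binary cross-entropy and Adam (lr $10^{-3}$,
batch 16).  Filter counts (32, 64), the dense width and the optimiser
settings are fixed in `cnn_spec()` so every reported number is
reproducible from configuration.  Because the learning-rate-reduction
(factor 0.5, patience 5) and early-stopping (patience 10, restore best
weights) callbacks need something to monitor, each training fold holds out
a stratified 10 % inner validation split.  The implementation is compiled
(RcppArmadillo, im2col + GEMM convolutions) with a private mt19937 random
stream, so a fit is bit-identical given its seed, on any platform.

Evaluation is stratified $k$-fold cross-validation (default $k=10$,
`repeats = 1`) at the fixed 0.5 probability threshold, reporting
accuracy, precision, recall and F1 per fold, and their mean with the
*population* standard deviation over all fold values, formatted
`"0.8700 (0.0557)"`.  Ratios with zero denominators are reported as 0 and
flagged rather than propagated as `NaN`.  Stratification keeps every
fold's class proportion within one sample of the global proportion, and
the layout is always fitted without labels before `cross_validate()` is
called, so no target information can leak through the image transform.

## Reproduction scale

The full study conditions ($p = 2500$, a 50×50 grid, ten CV repetitions)
are the generator and protocol defaults.  The bundled reproduction runs
(`scripts/acceptance.R` and the acceptance tests) use a desk-scale
configuration chosen by a fixed rule — the largest square grid whose full
five-cell sweep finishes comfortably within a coffee-break runtime on one
CPU: $n = 200$, $p = 900$ (100 signal + 800 noise) on a 30×30 grid, one
CV repetition, and a 30-epoch cap per fold.  The 24-cell
structural-alignment grid (four models × six metrics) runs at $p = 196$
(14×14) with a 20-epoch cap for the same reason.  Scaling down the noise
block moves the noise-to-signal ratio from 24:1 to 8:1, which makes some
cells *easier* than at full scale — the correlation model is the most
sensitive to this, and its reproduced accuracy should be read with that
in mind.  All scales are parameters: rerunning at $p = 2500$ requires
only changing `p` and the grid.

## Numerical choices

* Rank matrices are integer; `err` accumulates in doubles (exact for the
  magnitudes reached at these problem sizes; the incremental-vs-full
  equality test is exercised at small $p$ where both are exactly
  representable).
* Batch-norm uses $\epsilon = 10^{-5}$ and momentum 0.9 for running
  statistics; inference always uses running statistics.
* Cross-entropy probabilities are clamped to $[10^{-7}, 1-10^{-7}]$.
* A trailing minibatch of size 1 is dropped (batch statistics are
  undefined on a single sample).
* He-style weight initialisation; Box-Muller normals from the package's
  own mt19937 stream (the C++ standard specifies the mt19937 sequence
  exactly; `std::normal_distribution` is implementation-defined and is
  not used).
* PNG export quantises round-half-up to 8 bits; the RDS bundle format is
  lossless and is what the tests round-trip through.

## Known limitations

* The swap search is greedy; on adversarial instances it can stall above
  the global optimum (the test suite only requires it never *beats* the
  exhaustive optimum and never accepts a worsening swap).
* RD and the JS divergence (as opposed to its square root) are not true
  metrics; they are offered because they are standard practice, not
  because they satisfy metric axioms.
* GD depends on $k$; too small a $k$ fragments the graph (bridging then
  dominates), too large a $k$ collapses GD to ED.  The default $k = 10$
  is a conventional ISOMAP-style choice, not a tuned value.
* The CNN harness is binary-only by design, with no hyperparameter
  search, augmentation or multi-class head.

## A minimal session

```{r example}
library(igtdx)

ds <- simulate_igtd_model("tropical", n = 200, p = 900, seed = 1)
imgs <- igtd_convert(ds, metric = "TD")           # 30x30 grid inferred
report <- cross_validate(imgs, cnn_spec(max_epochs = 30), folds = 10,
                         seed = 1)
report
format_cv_table(list(`tropical/TD` = report))

render_rank_heatmap(rank_matrix(feature_distance(ds, "TD")),
                    "tropical_rank.png")
render_class_panels(imgs, "tropical_classes.png")
```
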