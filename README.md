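# igtdx

Tabular-to-image conversion for CNN classification, with non-Euclidean
feature metrics.

High-dimensional feature tables — bulk or single-cell expression matrices,
proteomic profiles, any samples-by-features numeric table — have no spatial
structure for a convolutional network to exploit. `igtdx` converts such
tables into grayscale *pseudo-images*: each feature is assigned to one
pixel of an `Nr x Nc` grid (`Nr * Nc = p`) so that the **ranking** of
pairwise feature dissimilarities matches the ranking of pixel distances as
closely as possible, and each sample's (min-max scaled) feature vector is
then rendered at those pixels. Formally, with `R` the rank matrix of
feature distances and `Q` the rank matrix of Euclidean pixel distances,
the layout minimises

    err(R', Q) = sum_{i>j} (r_ij - q_ij)^2

over synchronous row/column permutations of `R`, by greedy pairwise swaps
with an exact O(p) incremental update.

Because only distance *ranks* enter the objective, the feature metric is
pluggable. Six are built in, selected by name everywhere:

| name | dissimilarity | suited to |
|------|---------------|-----------|
| `ED` | Euclidean | commensurate, linearly related features |
| `RD` | 1 − Pearson correlation | linear co-expression structure |
| `GD` | kNN-graph shortest paths (ISOMAP-style, single-linkage bridging) | nonlinear manifolds |
| `JD` | Jensen–Shannon divergence of per-feature PMFs (base-2, in [0,1]) | compositional / probability-like features |
| `WD` | 1-D Wasserstein distance (quantile form over order statistics) | distributional location/shape differences |
| `TD` | tropical (max-plus) distance, `max_k(x−y) − min_k(x−y)` | shift-invariant dominance patterns |

The package also ships the six metric-aligned simulation generators
(i.i.d. Gaussian + logistic labels; Toeplitz-correlated Gaussian;
Swiss-roll manifold with geodesic-threshold labels; class-conditional
Dirichlet compositions; sorted-Gaussian quantile vectors with a W1 median
split; segment-plateau vectors with class-shifted segments) and a compact
two-block CNN (compiled, deterministic under a seed) with repeated
stratified k-fold cross-validation reporting accuracy, precision, recall
and F1 as `"mean (sd)"`.

## Worked example

Simulate the tropical segment-shift model, convert it with the matched
metric, and score the images by 10-fold CV:

```r
library(igtdx)

ds   <- simulate_igtd_model("tropical", n = 200, p = 900, seed = 1)
imgs <- igtd_convert(ds, metric = "TD")   # 30x30 grid inferred from p
rep_ <- cross_validate(imgs, cnn_spec(max_epochs = 30), folds = 10, seed = 1)
rep_
#> igtd_cvreport: 10-fold CV x 1 repeat(s)
#>   accuracy  0.9747 (0.0412)
#>   precision 0.9818 (0.0545)
#>   recall    0.9639 (0.0786)
#>   f1        0.9698 (0.0498)
```

Each line is the mean over the ten held-out folds with the population
standard deviation in parentheses: here the CNN recovers the class from
the tropical-metric images on ~97 % of held-out samples. The layout is
fitted without labels, so nothing about the classes leaks into the image
transform. Diagnostics mirror the method's standard visuals:

```r
render_rank_heatmap(rank_matrix(feature_distance(ds, "TD")), "rank.png")
render_class_panels(imgs, "classes.png")   # class 0 top row, class 1 bottom
```

A thin CLI wraps the same functions
(`inst/scripts/igtdx simulate|convert|evaluate|visualize|benchmark`), and
`load_table()` reads any delimited table with a binary label column, so
the identical pipeline runs on real expression matrices.

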