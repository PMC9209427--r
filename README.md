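# forestfire

Forest Fire Clustering for single-cell and other high-dimensional data:
graph-based clustering by label propagation with heat-versus-threshold
dynamics, per-point confidence estimation by Monte Carlo label permutation,
and inductive (online) assignment of newly arrived points.

Cell-type discovery in single-cell transcriptomics needs a clusterer that
makes weak assumptions about cluster shape, exposes one interpretable
resolution knob, and — unlike nearly all standard methods — can say *how
confident it is about each point's label*. Forest Fire Clustering addresses
this by treating clustering as fire spreading on a K-nearest-neighbour
affinity graph, and validating the result by re-burning the forest from
random seeds.

## The method

Given affinities `A[i,j] ∈ [0,1]` on a KNN graph (adaptive kernel with
per-vertex bandwidths calibrated to `log2(K)`, or a fixed Gaussian kernel;
fuzzy-union symmetrised):

* each vertex has acceptance threshold `T_i = 1 / D_i`, the inverse of its
  weighted degree `D_i = Σ_j A[i,j]`;
* during propagation of cluster `k` at fire temperature `c`, an unlabeled
  vertex `i` feels the average influence `H̄_i = c · mean_{j∈k} A[i,j]`,
  averaged over **all** current members of the cluster, and joins when
  `H̄_i ≥ T_i`;
* the fire dies when no unlabeled vertex crosses its threshold; the next seed
  is the unlabeled vertex that felt the least heat from the finished cluster;
  repeat until all points are labeled.

The fire temperature `c` is the single effective hyperparameter (a resolution
knob: cluster count is non-increasing in `c`). Monte Carlo validation re-runs
single-label propagations from uniformly drawn seeds and tabulates per-point
posterior label distributions, yielding a posterior exclusion probability
(PEP; filter at `PEP < 0.1` for high-confidence labels) and a label entropy
that is high at cluster boundaries and transitional cells.

## Worked example

Cluster-number discovery works best on a nonlinear embedding (see the
vignette for why the affinity kernel makes this matter):

```r
library(forestfire)

sim <- sim_circle_gaussians(n = 500, n_clusters = 8, sigma = 0.15, seed = 42)
set.seed(7)
emb <- uwot::umap(sim$X, n_neighbors = 15)

fit <- forest_fire(emb, temperature = 50, K = 50, seed = 1)
fit
#> Forest Fire Clustering
#>   n = 500  clusters = 8  temperature = 50
#>   cluster sizes: 82 74 60 65 43 56 70 50

purity(labels(fit), sim$truth)   # 0.986
ari(labels(fit), sim$truth)      # 0.969

post <- mc_validate(fit, trials = 2000, seed = 1)
post
#> Forest fire Monte Carlo posterior
#>   points: 500  clusters: 8  trials: 2000  pep mode: normalized
#>   PEP quartiles: 0 0 0 0 0
#>   high-confidence (PEP < 0.1): 500 points
```

Eight Gaussians on the unit circle come back as exactly eight clusters
(purity 0.986), and on the embedding every label is high-confidence — on the
raw overlapping coordinates the same machinery instead reports elevated PEP
and entropy at the cluster boundaries. `plot(fit)` draws the heat trace
(average heat at each acceptance, one rising-then-reset segment per
discovered cluster); `predict(fit, new_points)` assigns newcomers against the
frozen clustering and can seed brand-new clusters. A thin command-line
wrapper ships in `inst/scripts/ffc`
(`ffc cluster | validate | online | simulate | eval`).

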