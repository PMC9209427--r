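# Clustering evaluation metrics.

#' Purity of a predicted clustering against reference labels
#'
#' Builds the confusion matrix between predicted clusters and reference
#' classes, takes each predicted cluster's dominant reference-class count, and
#' divides the sum of dominant counts by the total number of points. Ranges
#' from the chance floor (one cluster, balanced classes gives 1/#classes) to 1
#' (every predicted cluster pure).
#'
#' @param pred Predicted cluster labels.
#' @param truth Reference labels (same length).
#' @return Scalar in \[0, 1\].
#' @export
purity <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("length mismatch: ", length(pred), " predictions vs ",
         length(truth), " reference labels")
  }
  conf <- table(pred, truth)
  sum(apply(conf, 1, max)) / length(pred)
}

#' Adjusted Rand index
#'
#' The Rand index (pairwise agreement between two partitions) adjusted for
#' chance; 1 for identical partitions (up to label permutation), about 0 for
#' independent ones. Delegates to [mclust::adjustedRandIndex()].
#'
#' @param pred,truth Two label vectors of equal length.
#' @return Scalar ARI.
#' @export
ari <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("length mismatch: ", length(pred), " vs ", length(truth), " labels")
  }
  mclust::adjustedRandIndex(pred, truth)
}

#' Mean silhouette width
#'
#' Average silhouette width of a labelling over Euclidean distances in `X`
#' (via [cluster::silhouette()]); in \[-1, 1\], higher is better. Requires at
#' least two clusters.
#'
#' @param X Numeric data matrix.
#' @param labels Cluster labels for the rows of `X`.
#' @return Scalar mean silhouette width.
#' @export
silhouette_score <- function(X, labels) {
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2L) {
    stop("silhouette requires at least 2 clusters")
  }
  sil <- cluster::silhouette(labels, stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Gaussian mixture model baseline clustering
#'
#' Fits a `G`-component Gaussian mixture with full covariances by EM,
#' initialised from a single random k-means start and run with the
#' conventional stopping rule for this baseline (relative log-likelihood
#' tolerance 1e-3, at most 100 iterations — the defaults shared by the common
#' mixture-model implementations). Distribution-based baselines like this
#' fail on non-convex shapes (concentric rings, half-moons), which is the
#' comparison the shape benchmarks exercise.
#'
#' @param X Numeric data matrix.
#' @param G Number of mixture components.
#' @param seed RNG seed for the k-means initialisation.
#' @param tol,itmax EM stopping controls.
#' @return Integer vector of component assignments.
#' @importFrom mclust me meVVV unmap emControl
#' @export
gmm_baseline <- function(X, G = 2L, seed = 0L, tol = 1e-3, itmax = 100L) {
  withr::with_seed(seed, {
    km <- stats::kmeans(X, centers = G, nstart = 1)
    z <- mclust::unmap(km$cluster)
    fit <- mclust::me(data = X, modelName = "VVV", z = z,
                      control = mclust::emControl(tol = tol, itmax = itmax))
    apply(fit$z, 1, which.max)
  })
}
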