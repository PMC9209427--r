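# Shared fixtures, all generated in code under fixed seeds.

# Two well-separated isotropic blobs; ground truth 1/2.
two_blobs <- function(n_per = 50, sep = 5, sd = 0.3, seed = 5) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per, 0, sd), n_per, 2),
               matrix(rnorm(2 * n_per, sep, sd), n_per, 2))
  })
  list(X = X, truth = rep(1:2, each = n_per))
}

# Wrap an explicit symmetric affinity matrix as an ffc_graph (for hand
# oracles on tiny graphs).
manual_graph <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  d <- Matrix::rowSums(A)
  structure(list(affinity = A, degree = d, threshold = 1 / d,
                 K = nrow(A) - 1L, kernel = list(mode = "manual", sigma = NULL),
                 symmetrization = "union", ids = NULL),
            class = "ffc_graph")
}

# The 8-Gaussian unit-circle fixture and a seeded UMAP embedding of it,
# computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

circle_fixture <- function(sigma = 0.15, seed = 42) {
  key <- paste0("circ_", sigma, "_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- sim_circle_gaussians(n = 500, n_clusters = 8,
                                                  sigma = sigma, seed = seed)
  }
  .fixture_cache[[key]]
}

circle_embedding <- function(sigma = 0.15, seed = 42, umap_seed = 7) {
  key <- paste0("emb_", sigma, "_", seed, "_", umap_seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- circle_fixture(sigma, seed)
    set.seed(umap_seed)
    .fixture_cache[[key]] <- uwot::umap(sim$X, n_neighbors = 15)
  }
  .fixture_cache[[key]]
}

# Independent brute-force oracle for one label propagation: dense synchronous
# sweeps computed with plain loops, no package internals.
oracle_propagate <- function(A, thr, labels, seed, cid, temp) {
  A <- as.matrix(A)
  labels[seed] <- cid
  repeat {
    members <- which(labels == cid)
    changed <- FALSE
    accept <- c()
    for (i in which(labels == 0)) {
      avg <- temp * sum(A[i, members]) / length(members)
      if (avg >= thr[i]) accept <- c(accept, i)
    }
    if (length(accept) == 0) break
    labels[accept] <- cid
  }
  labels
}
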