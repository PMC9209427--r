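#' Full pairwise Euclidean distance matrix
#'
#' Computes the dense n x n matrix of L2 distances between the rows of a
#' numeric matrix. Intended for small-to-moderate data; beyond `cap` rows the
#' dense matrix is refused and [knn_search()] should be used instead.
#'
#' @param x Numeric matrix (observations in rows). Must be finite, n >= 2.
#' @param cap Maximum number of rows for which the dense matrix is computed.
#' @return A symmetric n x n matrix with zero diagonal.
#' @export
l2_distances <- function(x, cap = 20000L) {
  x <- as_data_matrix(x)
  n <- nrow(x)
  if (n > cap) {
    stop("n = ", n, " exceeds the exact-mode cap (", cap,
         "); use knn_search() for a K-sparse neighbourhood instead.")
  }
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  # kill floating-point asymmetry so downstream symmetry checks are exact
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (!is.null(rownames(x))) dimnames(d) <- list(rownames(x), rownames(x))
  d
}

# Validate and coerce the input data matrix (cells x features).
as_data_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("data matrix must be numeric")
  if (nrow(x) < 2L) stop("need at least 2 observations, got ", nrow(x))
  if (any(!is.finite(x))) stop("data matrix contains missing or non-finite values")
  x
}

#' K-nearest-neighbour search
#'
#' Finds, for every observation, its `K` nearest neighbours under the L2
#' distance. `exact = TRUE` uses a blocked brute-force scan (always exact);
#' `exact = FALSE` delegates to an approximate kd-tree search
#' ([RANN::nn2()] with a nonzero error bound), appropriate for large n.
#'
#' @param x Numeric matrix (observations in rows).
#' @param K Number of neighbours, `1 <= K < n`. The point itself is never
#'   listed among its neighbours.
#' @param exact Logical; exact brute-force (default) or approximate search.
#' @param eps Approximation slack passed to the kd-tree search when
#'   `exact = FALSE`.
#' @param block Row-block size for the brute-force scan.
#' @return An object of class `ffc_knn`: a list with integer matrix `idx`
#'   (n x K neighbour indices), numeric matrix `dist` (n x K nondecreasing
#'   distances per row), `K`, and `ids` (row names, possibly `NULL`).
#' @export
knn_search <- function(x, K = 50L, exact = TRUE, eps = 0.1, block = 512L) {
  x <- as_data_matrix(x)
  n <- nrow(x)
  K <- as.integer(K)
  if (K < 1L || K >= n) {
    stop("K must satisfy 1 <= K < n; got K = ", K, " with n = ", n)
  }
  if (exact) {
    idx <- matrix(0L, n, K)
    dst <- matrix(0, n, K)
    sq <- rowSums(x^2)
    starts <- seq(1L, n, by = block)
    for (s in starts) {
      rows <- s:min(s + block - 1L, n)
      d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(x[rows, , drop = FALSE], x)
      d2[d2 < 0] <- 0
      d2[cbind(seq_along(rows), rows)] <- Inf  # exclude self
      for (r in seq_along(rows)) {
        o <- order(d2[r, ])[seq_len(K)]
        idx[rows[r], ] <- o
        dst[rows[r], ] <- sqrt(d2[r, o])
      }
    }
  } else {
    nn <- RANN::nn2(x, x, k = K + 1L, eps = eps)
    idx <- matrix(0L, n, K)
    dst <- matrix(0, n, K)
    for (r in seq_len(n)) {
      cand <- nn$nn.idx[r, ]
      drop_at <- match(r, cand)
      if (is.na(drop_at)) drop_at <- K + 1L  # self lost among duplicates
      keep <- seq_len(K + 1L)[-drop_at]
      idx[r, ] <- cand[keep]
      dst[r, ] <- nn$nn.dists[r, keep]
    }
  }
  structure(list(idx = idx, dist = dst, K = K, ids = rownames(x)),
            class = "ffc_knn")
}

#' Adaptive per-vertex kernel bandwidths (smooth-KNN calibration)
#'
#' For each vertex i, finds the bandwidth `sigma_i` such that
#' `sum_j exp(-max(d_ij - rho_i, 0) / sigma_i) = log2(K)`, where `rho_i` is the
#' distance to the nearest neighbour. This is the smoothed-KNN-distance
#' convention used by UMAP-style preprocessing: each vertex's kernel is scaled
#' to its local density, so affinities decay at a locally calibrated rate.
#'
#' The root is found by a vectorised binary search (bracket doubling followed
#' by bisection). Rows whose distances are all equal to `rho_i` (e.g. exact
#' duplicates) admit no root; their bandwidth is clamped to a tiny positive
#' value and a warning is raised when the whole row is zero-distance.
#'
#' @param knn An `ffc_knn` object with `K >= 2`.
#' @param tol Residual tolerance on the normalisation.
#' @param max_iter Bisection iterations.
#' @return List with `sigma` (n-vector, > 0) and `rho` (n-vector of nearest
#'   neighbour distances).
#' @export
adaptive_bandwidths <- function(knn, tol = 1e-5, max_iter = 100L) {
  stopifnot(inherits(knn, "ffc_knn"))
  if (knn$K < 2L) stop("adaptive bandwidths need K >= 2")
  d <- knn$dist
  n <- nrow(d)
  rho <- d[, 1L]
  if (any(zero_rows <- (d[, knn$K] <= 0))) {
    warning(sum(zero_rows), " vertices have all-zero neighbour distances; ",
            "their bandwidth is clamped to the smallest positive scale")
  }
  adj <- pmax(d - rho, 0)
  target <- log2(knn$K)
  f <- function(sig) rowSums(exp(-adj / sig))  # increasing in sig
  lo <- rep(1e-12, n)
  hi <- rep(1, n)
  for (it in 1:64) {
    need <- f(hi) < target
    if (!any(need)) break
    hi[need] <- hi[need] * 2
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- f(mid)
    up <- val < target
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    if (max(abs(val - target)) < tol && it > 8L) break
  }
  sigma <- (lo + hi) / 2
  sigma[sigma <= 0] <- .Machine$double.eps
  list(sigma = sigma, rho = rho)
}

#' Build the K-sparse symmetric affinity graph
#'
#' Converts KNN distances into kernel affinities and symmetrises them into a
#' sparse graph, then derives the per-vertex weighted degree `D_i` (row sum of
#' the affinity matrix, self-affinity excluded) and the label-acceptance
#' threshold `T_i = 1 / D_i`. Dense regions have high degree and therefore a
#' low threshold, which is what lets label propagation drift towards high
#' data density and stall in sparse boundary regions.
#'
#' Kernels:
#' \describe{
#'   \item{adaptive}{`a_ij = exp(-max(d_ij - rho_i, 0) / sigma_i)` with
#'     per-vertex bandwidths from [adaptive_bandwidths()].}
#'   \item{gaussian}{`a_ij = exp(-d_ij^2 / (2 sigma^2))` with one fixed
#'     bandwidth `sigma`.}
#' }
#' Symmetrisation: `"union"` (default) is the fuzzy-set union
#' `a + a' - a a'`; `"max"` takes the elementwise maximum.
#'
#' @param knn An `ffc_knn` object.
#' @param kernel `"adaptive"` or `"gaussian"`.
#' @param sigma Fixed bandwidth, required (> 0) for the Gaussian kernel.
#' @param symmetrization `"union"` or `"max"`.
#' @param bandwidths Optional precomputed result of [adaptive_bandwidths()].
#' @return An object of class `ffc_graph`: list with sparse symmetric
#'   `affinity` (dgCMatrix, entries in \[0, 1\], zero diagonal), `degree`,
#'   `threshold`, `K`, `kernel` spec and `ids`.
#' @export
build_affinity <- function(knn,
                           kernel = c("adaptive", "gaussian"),
                           sigma = NULL,
                           symmetrization = c("union", "max"),
                           bandwidths = NULL) {
  stopifnot(inherits(knn, "ffc_knn"))
  kernel <- match.arg(kernel)
  symmetrization <- match.arg(symmetrization)
  n <- nrow(knn$idx)
  K <- knn$K
  if (kernel == "adaptive") {
    if (is.null(bandwidths)) bandwidths <- adaptive_bandwidths(knn)
    vals <- exp(-pmax(knn$dist - bandwidths$rho, 0) / bandwidths$sigma)
  } else {
    if (is.null(sigma) || sigma <= 0) {
      stop("the Gaussian kernel requires sigma > 0")
    }
    vals <- exp(-knn$dist^2 / (2 * sigma^2))
  }
  A1 <- Matrix::sparseMatrix(i = rep(seq_len(n), times = K),
                             j = as.vector(knn$idx),
                             x = as.vector(vals),
                             dims = c(n, n))
  Matrix::diag(A1) <- 0
  At <- Matrix::t(A1)
  A <- if (symmetrization == "union") {
    A1 + At - A1 * At
  } else {
    (A1 + At + abs(A1 - At)) / 2
  }
  A <- Matrix::drop0(A)
  degree <- Matrix::rowSums(A)
  if (any(degree <= 0)) {
    stop(sum(degree <= 0), " isolated vertices (zero weighted degree); ",
         "increase K so every point is connected")
  }
  structure(list(affinity = A,
                 degree = degree,
                 threshold = 1 / degree,
                 K = K,
                 kernel = list(mode = kernel, sigma = sigma,
                               bandwidths = if (kernel == "adaptive") bandwidths),
                 symmetrization = symmetrization,
                 ids = knn$ids),
            class = "ffc_graph")
}

#' One-call affinity graph from a data matrix or embedding
#'
#' Convenience wrapper: [knn_search()] followed by [build_affinity()]. The
#' matrix is used as-is; any normalisation, log-transform or dimensionality
#' reduction is the caller's responsibility (for scRNA-seq, pass a
#' low-dimensional embedding such as PCA or UMAP coordinates).
#'
#' @inheritParams knn_search
#' @inheritParams build_affinity
#' @return An `ffc_graph` object.
#' @export
affinity_graph <- function(x, K = 50L,
                           kernel = c("adaptive", "gaussian"),
                           sigma = NULL,
                           symmetrization = c("union", "max"),
                           exact = TRUE) {
  knn <- knn_search(x, K = K, exact = exact)
  build_affinity(knn, kernel = match.arg(kernel), sigma = sigma,
                 symmetrization = match.arg(symmetrization))
}

#' @export
print.ffc_graph <- function(x, ...) {
  n <- nrow(x$affinity)
  cat("Forest fire affinity graph\n")
  cat("  vertices:", n, " K:", x$K, " kernel:", x$kernel$mode,
      if (!is.null(x$kernel$sigma)) paste0("(sigma = ", x$kernel$sigma, ")"),
      "\n")
  cat("  symmetrization:", x$symmetrization,
      " nonzeros:", Matrix::nnzero(x$affinity), "\n")
  cat("  weighted degree: [", signif(min(x$degree), 4), ", ",
      signif(max(x$degree), 4), "]\n", sep = "")
  invisible(x)
}
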