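# Seeded synthetic-data generators. Every generator is a pure function of its
# arguments plus the seed, and returns an `ffc_sim` list: X (matrix), truth
# (integer ground-truth groups), optional pseudotime, and the generator spec.

new_sim <- function(X, truth, pseudotime = NULL, spec = list()) {
  structure(list(X = X, truth = as.integer(truth), pseudotime = pseudotime,
                 spec = spec),
            class = "ffc_sim")
}

#' Gaussian mixtures evenly spaced on the unit circle
#'
#' Samples `n` points from `n_clusters` isotropic 2-D Gaussians whose centres
#' sit at angles `2*pi*j / n_clusters` on the unit circle (the first centre at
#' (1, 0)), with equal-probability cluster assignment. A subset of centres can
#' be selected with `keep` (e.g. every other centre of an 8-cluster layout for
#' train/test experiments), and arbitrary centres can be supplied via
#' `centers`.
#'
#' @param n Total number of points.
#' @param n_clusters Number of mixture components.
#' @param sigma Common isotropic standard deviation.
#' @param seed RNG seed.
#' @param keep Optional integer subset of `1:n_clusters` selecting which
#'   centres are actually sampled (truth labels keep their original ids).
#' @param centers Optional explicit k x 2 matrix of centres overriding the
#'   circle layout.
#' @return An `ffc_sim` with 2-D `X` and `truth`.
#' @export
sim_circle_gaussians <- function(n = 500L, n_clusters = 8L, sigma = 0.15,
                                 seed = 0L, keep = NULL, centers = NULL) {
  if (is.null(centers)) {
    ang <- 2 * pi * seq_len(n_clusters) / n_clusters
    centers <- cbind(cos(ang), sin(ang))
  }
  if (n < nrow(centers) && is.null(keep)) {
    stop("n must be at least the number of clusters")
  }
  ids <- if (is.null(keep)) seq_len(nrow(centers)) else as.integer(keep)
  withr::with_seed(seed, {
    truth <- sample(ids, n, replace = TRUE)
    X <- centers[truth, , drop = FALSE] +
      matrix(stats::rnorm(2 * n, sd = sigma), n, 2)
  })
  new_sim(X, truth, spec = list(family = "circle_gaussians", n = n,
                                n_clusters = n_clusters, sigma = sigma,
                                seed = seed, keep = keep))
}

#' 2-D shape benchmark datasets
#'
#' The conventional two-dimensional clustering benchmarks: `"rings"` (two
#' concentric circles, inner radius `factor` times the outer), `"moons"` (two
#' interleaved half-circles), `"blobs"` (three isotropic Gaussians) and
#' `"aniso"` (the blobs sheared by a fixed linear map). Class sizes are
#' balanced up to one point. Noise is isotropic Gaussian jitter on the
#' coordinates.
#'
#' @param kind One of `"rings"`, `"moons"`, `"blobs"`, `"aniso"`.
#' @param n Total number of points.
#' @param noise Gaussian jitter standard deviation (rings and moons).
#' @param seed RNG seed.
#' @param factor Inner/outer radius ratio for `"rings"`.
#' @return An `ffc_sim` with 2-D `X` and `truth`.
#' @export
sim_shapes <- function(kind = c("rings", "moons", "blobs", "aniso"),
                       n = 1000L, noise = 0.05, seed = 0L, factor = 0.5) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown kind '", kind[1],
                     "'; available kinds: rings, moons, blobs, aniso"))
  if (n < 4L) stop("n must be at least 4")
  n1 <- ceiling(n / 2); n2 <- n - n1
  withr::with_seed(seed, {
    if (kind == "rings") {
      t1 <- seq(0, 2 * pi, length.out = n1 + 1L)[-1L]
      t2 <- seq(0, 2 * pi, length.out = n2 + 1L)[-1L]
      X <- rbind(cbind(cos(t1), sin(t1)),
                 factor * cbind(cos(t2), sin(t2)))
      truth <- rep(1:2, c(n1, n2))
    } else if (kind == "moons") {
      t1 <- seq(0, pi, length.out = n1)
      t2 <- seq(0, pi, length.out = n2)
      X <- rbind(cbind(cos(t1), sin(t1)),
                 cbind(1 - cos(t2), 1 - sin(t2) - 0.5))
      truth <- rep(1:2, c(n1, n2))
    } else {
      centers <- matrix(c(-6, -4, 0, 5, 6, -6), 3, 2, byrow = TRUE)
      n3 <- floor(n / 3)
      sizes <- c(n - 2L * n3, n3, n3)
      truth <- rep(1:3, sizes)
      X <- centers[truth, ] + matrix(stats::rnorm(2 * n), n, 2)
      if (kind == "aniso") {
        X <- X %*% matrix(c(0.6, -0.6, -0.4, 0.8), 2, 2)
      }
    }
    if (kind %in% c("rings", "moons") && noise > 0) {
      X <- X + matrix(stats::rnorm(2 * n, sd = noise), n, 2)
    }
  })
  new_sim(X, truth, spec = list(family = "shapes", kind = kind, n = n,
                                noise = noise, factor = factor, seed = seed))
}

# Expected per-gene means for one branch of a paths-mode simulation at
# pseudotime t: log-linear interpolation between the shared origin profile
# (t = 0) and the branch's DE endpoint profile (t = 1).
path_means <- function(origin_means, branch_means, t) {
  exp((1 - t) * log(origin_means) + t * log(branch_means))
}

#' Splatter-style scRNA-seq count simulation (minimal emulator)
#'
#' Generates a cells x genes count matrix with the negative-binomial-like
#' structure of the Splatter simulator: gene base means drawn from a Gamma
#' distribution, expression-outlier genes inflated by log-normal factors,
#' per-group differential expression via log-normal fold changes, Gamma
#' cell-size factors with Poisson sampling (negative-binomial marginal), and
#' an optional `"paths"` mode in which group mean profiles are reached by
#' log-linear interpolation from a shared origin along a pseudotime in
#' \[0, 1\]. Dropout and mean-variance (BCV) trends are deliberately not
#' modelled.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param group_probs Probability simplex over groups (or paths).
#' @param de_prob Probability a gene is differentially expressed in a group.
#' @param de_facLoc,de_facScale Log-normal location/scale of DE fold changes
#'   (each DE factor is inverted with probability 1/2 to give down-regulation).
#' @param out_prob Probability a gene is an expression outlier.
#' @param out_facLoc,out_facScale Log-normal location/scale of outlier factors
#'   applied to the median base mean.
#' @param mode `"groups"` (discrete cell types) or `"paths"` (continuous
#'   differentiation from a shared origin; pseudotime returned).
#' @param mean_shape,mean_rate Gamma parameters of gene base means.
#' @param lib_loc,lib_scale Log-normal parameters of expected library sizes.
#' @param bcv Dispersion of the Gamma cell/gene noise (biological coefficient
#'   of variation); counts are Poisson-Gamma mixed per entry.
#' @param seed RNG seed.
#' @return An `ffc_sim` with integer count matrix `X` (cells x genes), `truth`
#'   (group/path), and `pseudotime` in paths mode.
#' @export
sim_splatter_like <- function(n_cells = 1000L, n_genes = 5000L,
                              group_probs = c(0.45, 0.15, 0.15, 0.15, 0.1),
                              de_prob = 0.1, de_facLoc = 0.1,
                              de_facScale = 0.4,
                              out_prob = 0.05, out_facLoc = 4,
                              out_facScale = 0.5,
                              mode = c("groups", "paths"),
                              mean_shape = 0.6, mean_rate = 0.3,
                              lib_loc = 9.5, lib_scale = 0.2,
                              bcv = 0.2, seed = 0L) {
  mode <- match.arg(mode)
  if (abs(sum(group_probs) - 1) > 1e-8) stop("group_probs must sum to 1")
  n_groups <- length(group_probs)
  withr::with_seed(seed, {
    base <- stats::rgamma(n_genes, shape = mean_shape, rate = mean_rate)
    out_gene <- stats::runif(n_genes) < out_prob
    out_fac <- exp(stats::rnorm(sum(out_gene), out_facLoc, out_facScale))
    base[out_gene] <- stats::median(base) * out_fac
    base <- pmax(base, 1e-8)

    # per-group log fold changes (0 for non-DE genes)
    lfc <- matrix(0, n_genes, n_groups)
    for (g in seq_len(n_groups)) {
      de <- stats::runif(n_genes) < de_prob
      fac <- stats::rnorm(sum(de), de_facLoc, de_facScale)
      fac <- fac * sample(c(1, -1), sum(de), replace = TRUE)
      lfc[de, g] <- fac
    }
    group_means <- base * exp(lfc)  # n_genes x n_groups

    truth <- sample.int(n_groups, n_cells, replace = TRUE, prob = group_probs)
    if (mode == "paths") {
      pseudotime <- stats::runif(n_cells)
      cell_means <- sapply(seq_len(n_cells), function(i) {
        path_means(base, group_means[, truth[i]], pseudotime[i])
      })  # n_genes x n_cells
    } else {
      pseudotime <- NULL
      cell_means <- group_means[, truth, drop = FALSE]
    }

    lib <- exp(stats::rnorm(n_cells, lib_loc, lib_scale))
    cell_means <- sweep(cell_means, 2, lib / colSums(cell_means), `*`)
    # biological noise: per-entry Gamma with squared CV = bcv^2
    if (bcv > 0) {
      shape <- 1 / bcv^2
      cell_means <- matrix(stats::rgamma(length(cell_means), shape = shape,
                                         rate = shape / pmax(cell_means, 1e-12)),
                           nrow(cell_means), ncol(cell_means))
    }
    counts <- matrix(stats::rpois(length(cell_means), cell_means),
                     nrow(cell_means), ncol(cell_means))
  })
  X <- t(counts)  # cells x genes
  rownames(X) <- paste0("cell", seq_len(n_cells))
  colnames(X) <- paste0("gene", seq_len(n_genes))
  new_sim(X, truth, pseudotime = pseudotime,
          spec = list(family = "splatter_like", n_cells = n_cells,
                      n_genes = n_genes, group_probs = group_probs,
                      de_prob = de_prob, de_facLoc = de_facLoc,
                      de_facScale = de_facScale, out_prob = out_prob,
                      out_facLoc = out_facLoc, out_facScale = out_facScale,
                      mode = mode, seed = seed))
}

#' @export
print.ffc_sim <- function(x, ...) {
  cat("Synthetic dataset (", x$spec$family, "): ",
      nrow(x$X), " x ", ncol(x$X), ", ",
      length(unique(x$truth)), " ground-truth groups",
      if (!is.null(x$pseudotime)) ", with pseudotime", "\n", sep = "")
  invisible(x)
}
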