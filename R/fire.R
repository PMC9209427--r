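# ---- heat accumulator -------------------------------------------------------
#
# The accumulator is a plain list: heat[i] is the running sum over the
# currently burning cluster's members j of temperature * A[i, j]; size is the
# member count. The average label influence at vertex i is heat[i] / size, a
# mean over ALL members including those with zero affinity to i — that
# dilution is what halts propagation at sparse cluster boundaries.

new_heat <- function(n) list(heat = numeric(n), size = 0L)

heat_add <- function(acc, graph, vertices, temperature) {
  acc$heat <- acc$heat + temperature *
    Matrix::rowSums(graph$affinity[, vertices, drop = FALSE])
  acc$size <- acc$size + length(vertices)
  acc
}

#' Average label influence at a vertex
#'
#' The mean pairwise label influence (fire temperature times affinity) between
#' vertex `vertex` and all current members of the burning cluster. The
#' denominator is the full cluster size: members with zero affinity to the
#' vertex still count, so influence is diluted as a cluster grows beyond the
#' vertex's neighbourhood.
#'
#' @param acc Heat accumulator (internal list with `heat` and `size`).
#' @param vertex Vertex index.
#' @return Nonnegative scalar.
#' @keywords internal
average_influence <- function(acc, vertex) {
  if (acc$size < 1L) stop("average influence undefined for an empty cluster")
  acc$heat[vertex] / acc$size
}

# ---- propagation ------------------------------------------------------------

#' Propagate one label from a seed vertex
#'
#' Lights `seed` with label `cluster_id` and spreads the label through the
#' graph until no remaining unlabeled vertex receives average influence at or
#' above its acceptance threshold. Vertices holding labels from earlier
#' propagations are exhausted and never change.
#'
#' Default semantics are synchronous sweeps: in each sweep, every unlabeled
#' vertex whose average influence from vertices labeled in *previous* sweeps
#' meets its threshold (`>=`, acceptance at equality) joins simultaneously;
#' heat sums and the cluster size are then updated once. This makes the fixed
#' point independent of vertex iteration order. `async = TRUE` instead labels
#' vertices one at a time in index order, updating heat immediately after each
#' acceptance.
#'
#' @param graph An `ffc_graph`.
#' @param labels Integer n-vector, 0 = unlabeled; nonzero entries are frozen.
#' @param seed Seed vertex index (must currently be unlabeled).
#' @param cluster_id Label to propagate.
#' @param temperature Fire temperature c > 0.
#' @param candidates Optional logical mask restricting which unlabeled
#'   vertices may accept the label (used by online assignment).
#' @param async Asynchronous vertex-at-a-time acceptance (non-default).
#' @return List with updated `labels`, `events` (data frame: vertex, sweep,
#'   avg_heat, is_seed), and the final accumulator `heat`/`size`.
#' @export
propagate <- function(graph, labels, seed, cluster_id, temperature,
                      candidates = NULL, async = FALSE) {
  n <- length(graph$degree)
  stopifnot(length(labels) == n, temperature > 0)
  if (labels[seed] != 0L) {
    stop("seed vertex ", seed, " is already labeled (", labels[seed], ")")
  }
  thr <- graph$threshold
  eligible <- labels == 0L
  if (!is.null(candidates)) eligible <- eligible & candidates
  labels[seed] <- cluster_id
  eligible[seed] <- FALSE
  acc <- new_heat(n)
  acc <- heat_add(acc, graph, seed, temperature)
  ev_vertex <- seed; ev_sweep <- 0L; ev_heat <- 0; ev_seed <- TRUE

  if (!async) {
    sweep <- 0L
    repeat {
      sweep <- sweep + 1L
      avg <- acc$heat / acc$size
      new <- which(eligible & avg >= thr)
      if (length(new) == 0L) break
      ev_vertex <- c(ev_vertex, new)
      ev_sweep <- c(ev_sweep, rep(sweep, length(new)))
      ev_heat <- c(ev_heat, avg[new])
      ev_seed <- c(ev_seed, rep(FALSE, length(new)))
      labels[new] <- cluster_id
      eligible[new] <- FALSE
      acc <- heat_add(acc, graph, new, temperature)
    }
  } else {
    pass <- 0L
    repeat {
      pass <- pass + 1L
      changed <- FALSE
      for (i in which(eligible)) {
        if (acc$heat[i] / acc$size >= thr[i]) {
          ev_vertex <- c(ev_vertex, i)
          ev_sweep <- c(ev_sweep, pass)
          ev_heat <- c(ev_heat, acc$heat[i] / acc$size)
          ev_seed <- c(ev_seed, FALSE)
          labels[i] <- cluster_id
          eligible[i] <- FALSE
          acc <- heat_add(acc, graph, i, temperature)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  list(labels = labels,
       events = data.frame(vertex = ev_vertex, sweep = ev_sweep,
                           avg_heat = ev_heat, is_seed = ev_seed),
       heat = acc$heat, size = acc$size)
}

#' Deterministic next-seed selection
#'
#' After a propagation finishes, the next cluster's seed is the unlabeled
#' vertex that experienced the *lowest* average influence from the cluster
#' just completed — a pessimistic estimate of the next cluster centre, in the
#' spirit of the method of conditional probabilities (cf. k-means++). Ties are
#' broken by the lowest vertex index.
#'
#' @param labels Integer label vector (0 = unlabeled).
#' @param acc Heat accumulator left by the previous cluster's propagation.
#' @return Vertex index.
#' @keywords internal
select_next_seed <- function(labels, acc) {
  cand <- which(labels == 0L)
  if (length(cand) == 0L) stop("no unlabeled vertex remains")
  avg <- acc$heat[cand] / acc$size
  cand[which.min(avg)]
}

# ---- fitting ----------------------------------------------------------------

#' Forest Fire Clustering
#'
#' Clusters the rows of a data matrix (or a prebuilt affinity graph) by
#' iterative label propagation. A random first seed is lit; its label spreads
#' while the average label influence `c * mean(A[i, members])` meets each
#' vertex's threshold `1 / D_i`; when the fire dies out, the next seed is the
#' unlabeled vertex least heated by the previous cluster, and the process
#' repeats until every vertex is labeled. The fire temperature `c` is the
#' single effective hyperparameter: larger `c` lets labels travel further and
#' yields fewer, larger clusters (analogous to a resolution parameter).
#'
#' @param x Numeric matrix (observations in rows) or an `ffc_graph` built with
#'   [affinity_graph()]. Pass coordinates or a low-dimensional embedding, not
#'   raw counts; no internal normalisation is applied.
#' @param temperature Fire temperature c > 0.
#' @param K Neighbour count for graph construction (ignored if `x` is a graph).
#' @param kernel,sigma,symmetrization,exact Graph construction options, see
#'   [affinity_graph()].
#' @param first_seed Explicit first seed vertex index; if `NULL`, drawn
#'   uniformly under `seed`. All subsequent seeds are deterministic.
#' @param seed RNG seed for the first-seed draw.
#' @param async Use asynchronous vertex-at-a-time acceptance (non-default;
#'   see [propagate()]).
#' @return An object of class `forest_fire`: list with `labels` (1-based
#'   integer cluster ids), `k` (number of clusters), `seeds` (seed vertex per
#'   cluster), `trace` (acceptance-event log: order, vertex, cluster, sweep,
#'   avg_heat, is_seed), `temperature`, `graph`, `data` (the input matrix when
#'   one was given), and `call`.
#' @examples
#' sim <- sim_circle_gaussians(n = 200, n_clusters = 4, sigma = 0.1, seed = 1)
#' fit <- forest_fire(sim$X, temperature = 20, K = 20)
#' table(labels(fit), sim$truth)
#' @export
forest_fire <- function(x, temperature = 50, K = 50L,
                        kernel = c("adaptive", "gaussian"),
                        sigma = NULL,
                        symmetrization = c("union", "max"),
                        exact = TRUE,
                        first_seed = NULL, seed = 0L,
                        async = FALSE) {
  if (temperature <= 0) stop("fire temperature must satisfy c > 0")
  if (inherits(x, "ffc_graph")) {
    graph <- x
    data <- NULL
  } else {
    data <- as_data_matrix(x)
    graph <- affinity_graph(data, K = K, kernel = match.arg(kernel),
                            sigma = sigma,
                            symmetrization = match.arg(symmetrization),
                            exact = exact)
  }
  n <- length(graph$degree)
  labels <- integer(n)
  if (is.null(first_seed)) {
    first_seed <- withr::with_seed(seed, sample.int(n, 1L))
  }
  seeds <- integer(0)
  trace_parts <- list()
  cluster_id <- 0L
  seed_vertex <- as.integer(first_seed)
  repeat {
    cluster_id <- cluster_id + 1L
    seeds[cluster_id] <- seed_vertex
    res <- propagate(graph, labels, seed_vertex, cluster_id, temperature,
                     async = async)
    labels <- res$labels
    ev <- res$events
    ev$cluster <- cluster_id
    trace_parts[[cluster_id]] <- ev
    if (!any(labels == 0L)) break
    seed_vertex <- select_next_seed(labels, res)
  }
  trace <- do.call(rbind, trace_parts)
  trace <- data.frame(order = seq_len(nrow(trace)),
                      vertex = trace$vertex,
                      cluster = trace$cluster,
                      sweep = trace$sweep,
                      avg_heat = trace$avg_heat,
                      is_seed = trace$is_seed)
  structure(list(labels = labels, k = cluster_id, seeds = seeds,
                 trace = trace, temperature = temperature, graph = graph,
                 data = data, first_seed = as.integer(first_seed),
                 call = match.call()),
            class = "forest_fire")
}

#' Heat trace of a fitted clustering
#'
#' The ordered sequence of average-heat values at each label-acceptance event,
#' one entry per vertex. Clusters are discovered sequentially, so the trace
#' partitions into contiguous per-cluster segments; each reset-and-rise spike
#' corresponds to one discovered cluster (seeds are recorded with heat 0 and
#' flagged). Plot it as a quick diagnostic of how cleanly clusters ignited.
#'
#' @param result A `forest_fire` fit.
#' @return Data frame with columns order, vertex, cluster, sweep, avg_heat,
#'   is_seed.
#' @export
heat_trace <- function(result) {
  stopifnot(inherits(result, "forest_fire"))
  result$trace
}

#' @export
labels.forest_fire <- function(object, ...) object$labels

#' @export
print.forest_fire <- function(x, ...) {
  cat("Forest Fire Clustering\n")
  cat("  n =", length(x$labels), " clusters =", x$k,
      " temperature =", x$temperature, "\n")
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.forest_fire <- function(object, ...) {
  sizes <- tabulate(object$labels, object$k)
  non_seed <- object$trace$avg_heat[!object$trace$is_seed]
  out <- list(n = length(object$labels), k = object$k,
              temperature = object$temperature, sizes = sizes,
              seeds = object$seeds,
              heat_range = if (length(non_seed)) range(non_seed) else c(NA, NA))
  class(out) <- "summary.forest_fire"
  out
}

#' @export
print.summary.forest_fire <- function(x, ...) {
  cat("Forest Fire Clustering: n =", x$n, ", k =", x$k,
      ", temperature =", x$temperature, "\n")
  cat("cluster sizes:\n")
  print(stats::setNames(x$sizes, seq_along(x$sizes)))
  cat("seed vertices:", paste(x$seeds, collapse = " "), "\n")
  if (!anyNA(x$heat_range)) {
    cat("acceptance heat range: [", signif(x$heat_range[1], 4), ", ",
        signif(x$heat_range[2], 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Plot a fitted Forest Fire clustering
#'
#' `which = "trace"` draws the heat trace (average heat at each acceptance
#' event, coloured by cluster); `which = "clusters"` draws a 2-D scatter of
#' the data coloured by label (requires the fit to have been made from a
#' 2-column matrix, or `coords` to be supplied).
#'
#' @param x A `forest_fire` fit.
#' @param which `"trace"` or `"clusters"`.
#' @param coords Optional n x 2 matrix of plotting coordinates.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.forest_fire <- function(x, which = c("trace", "clusters"),
                             coords = NULL, ...) {
  which <- match.arg(which)
  if (which == "trace") {
    tr <- x$trace
    plot(tr$order, tr$avg_heat, col = tr$cluster, pch = 16, cex = 0.6,
         xlab = "acceptance order", ylab = "average heat at acceptance", ...)
    graphics::points(tr$order[tr$is_seed], tr$avg_heat[tr$is_seed],
                     pch = 4, cex = 1.2)
  } else {
    if (is.null(coords)) coords <- x$data
    if (is.null(coords) || ncol(coords) != 2L) {
      stop("cluster plot needs 2-D coordinates; supply `coords`")
    }
    plot(coords[, 1], coords[, 2], col = x$labels, pch = 16, cex = 0.6,
         xlab = "dim 1", ylab = "dim 2", ...)
  }
  invisible(x)
}

#' Cluster-definition certificate
#'
#' Checks the fixed-point property of a completed clustering: for every
#' cluster k and every vertex j outside k, the average label influence of k
#' on j must fall strictly below j's acceptance threshold. Vertices labeled in
#' propagations later than k are guaranteed to satisfy this by construction
#' (they stayed unlabeled through k's entire fire); vertices exhausted in
#' earlier propagations are reported too, since on well-separated data the
#' certificate holds globally.
#'
#' @param fit A `forest_fire` fit.
#' @return List with `ok` (all outside influences strictly below threshold),
#'   `worst_margin` (min over outside vertices of `T_j - influence`), and the
#'   per-cluster margin matrix is attached as `margins` (n x k, `NA` for
#'   members).
#' @export
fire_certificate <- function(fit) {
  stopifnot(inherits(fit, "forest_fire"))
  A <- fit$graph$affinity
  thr <- fit$graph$threshold
  n <- length(fit$labels)
  margins <- matrix(NA_real_, n, fit$k)
  for (k in seq_len(fit$k)) {
    members <- which(fit$labels == k)
    infl <- fit$temperature *
      Matrix::rowSums(A[, members, drop = FALSE]) / length(members)
    out <- fit$labels != k
    margins[out, k] <- thr[out] - infl[out]
  }
  list(ok = all(margins > 0, na.rm = TRUE),
       worst_margin = min(margins, na.rm = TRUE),
       margins = margins)
}
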