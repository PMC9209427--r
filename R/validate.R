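# Monte Carlo internal validation.
#
# Each trial clears every label, draws one seed vertex uniformly, re-lights it
# with the label it carried in the initial clustering, and lets that single
# label propagate to its fixed point. Tabulating which label (if any) each
# point receives across T trials gives a per-point empirical posterior label
# distribution, from which the posterior exclusion probability (PEP) and the
# label entropy are derived. Trials are independent, so the computation is
# embarrassingly parallel; per-trial seeds are pre-drawn from the master seed,
# making the tallies identical for any worker count.

#' One Monte Carlo validation trial
#'
#' Clears all labels, seeds vertex `r` (drawn by the caller) with its initial
#' cluster label, and propagates that single label to its fixed point.
#'
#' @param graph The `ffc_graph` used by the initial fit.
#' @param initial_labels Integer labels from the initial clustering.
#' @param r Seed vertex for this trial.
#' @param temperature Fire temperature; must match the initial fit.
#' @return List with `accepted` (vertex indices that took the label, seed
#'   included) and `label` (the propagated cluster id).
#' @export
mc_trial <- function(graph, initial_labels, r, temperature) {
  lab <- initial_labels[r]
  res <- propagate(graph, integer(length(initial_labels)), r, lab, temperature)
  list(accepted = which(res$labels == lab), label = lab)
}

#' Monte Carlo validation of a Forest Fire clustering
#'
#' Runs `trials` independent single-label propagations from uniformly drawn
#' seed vertices and tabulates, for every point, how often each initial
#' cluster label reached it. Derives the posterior exclusion probability
#' ([pep()]) and label entropy ([label_entropy()]) per point.
#'
#' Determinism: the per-trial seed vertices are pre-drawn from `seed`, and
#' shard tallies are merged by integer addition, so the result is identical
#' for any `workers` value.
#'
#' @param object A `forest_fire` fit.
#' @param trials Number of Monte Carlo trials (a few thousand gives stable
#'   estimates; more clusters need more trials).
#' @param workers Number of forked workers (unix only; 1 = sequential).
#' @param seed Master RNG seed.
#' @param pep_mode PEP definition, see [pep()].
#' @return An object of class `ffc_posterior`: list with integer `counts`
#'   (n x k), `trials`, `received` (trials in which each point got any label),
#'   `pep`, `entropy` (nats), `never_reached` flag vector, `initial` labels,
#'   `pep_mode` and `seed`.
#' @export
mc_validate <- function(object, trials = 2000L, workers = 1L, seed = 0L,
                        pep_mode = c("normalized", "raw", "coverage")) {
  stopifnot(inherits(object, "forest_fire"))
  pep_mode <- match.arg(pep_mode)
  trials <- as.integer(trials)
  if (trials < 1L) stop("need at least one trial")
  n <- length(object$labels)
  k <- object$k
  graph <- object$graph
  if (k == 1L) {
    warning("only one cluster in the initial fit: every trial can only ",
            "propagate that label, so PEP is identically zero and ",
            "uninformative")
  }
  seed_vertices <- withr::with_seed(seed, sample.int(n, trials, replace = TRUE))

  run_shard <- function(trial_ids) {
    counts <- matrix(0L, n, k)
    for (t in trial_ids) {
      tr <- mc_trial(graph, object$labels, seed_vertices[t],
                     object$temperature)
      counts[tr$accepted, tr$label] <- counts[tr$accepted, tr$label] + 1L
    }
    counts
  }

  workers <- max(1L, as.integer(workers))
  if (workers > 1L && .Platform$OS.type == "unix") {
    shards <- split(seq_len(trials), rep(seq_len(workers), length.out = trials))
    parts <- parallel::mclapply(shards, run_shard, mc.cores = workers)
    counts <- Reduce(`+`, parts)
  } else {
    counts <- run_shard(seq_len(trials))
  }

  post <- structure(list(counts = counts, trials = trials,
                         received = rowSums(counts),
                         initial = object$labels,
                         pep_mode = pep_mode, seed = seed),
                    class = "ffc_posterior")
  post$never_reached <- post$received == 0
  post$pep <- pep(post, mode = pep_mode)
  post$entropy <- label_entropy(post)
  post
}

#' Posterior exclusion probability
#'
#' Per-point probability that Monte Carlo propagation delivered a label other
#' than the point's initial one — low PEP means a high-confidence assignment.
#'
#' Modes:
#' \describe{
#'   \item{normalized}{(default) `1 - counts_i[S_i] / received_i`, the
#'     fraction of label-receiving trials that delivered a non-initial label;
#'     points never reached get PEP 1. This is the confidence measure meant by
#'     the usual `PEP < 0.1` filter.}
#'   \item{raw}{`1 - sum_{k != S_i} counts_i[k] / T`: the exclusion
#'     probability computed over all trials including those in which the point
#'     received no label at all (so isolated points score low, not high).}
#'   \item{coverage}{`1 - counts_i[S_i] / T`: one minus the fraction of all
#'     trials delivering the initial label.}
#' }
#'
#' @param posterior An `ffc_posterior`.
#' @param mode One of `"normalized"`, `"raw"`, `"coverage"`.
#' @return Numeric n-vector in \[0, 1\].
#' @export
pep <- function(posterior, mode = c("normalized", "raw", "coverage")) {
  stopifnot(inherits(posterior, "ffc_posterior"))
  if (is.character(mode)) {
    mode <- match.arg(mode)
  } else {
    stop("unknown pep mode; available modes: normalized, raw, coverage")
  }
  own <- posterior$counts[cbind(seq_along(posterior$initial),
                                posterior$initial)]
  received <- posterior$received
  switch(mode,
    normalized = ifelse(received > 0, 1 - own / received, 1),
    raw = 1 - (received - own) / posterior$trials,
    coverage = 1 - own / posterior$trials)
}

#' Label entropy of the posterior label distribution
#'
#' Shannon entropy (natural log) of each point's received-label frequencies,
#' normalised over the trials in which the point received any label; the
#' convention 0 log 0 = 0 applies. High entropy marks cluster boundaries and
#' transitional states (e.g. progenitor cells on a differentiation path);
#' points never reached by any trial get entropy 0 and are flagged in
#' `never_reached`.
#'
#' @param posterior An `ffc_posterior`.
#' @return Numeric n-vector in \[0, ln k\] (nats).
#' @export
label_entropy <- function(posterior) {
  stopifnot(inherits(posterior, "ffc_posterior"))
  p <- posterior$counts / pmax(posterior$received, 1L)
  lp <- ifelse(p > 0, log(p), 0)
  -rowSums(p * lp)
}

#' High-confidence label mask
#'
#' Points whose PEP is strictly below `threshold` (default 0.1, the
#' conventional confidence filter).
#'
#' @param posterior An `ffc_posterior`.
#' @param threshold Strict upper bound on PEP.
#' @return Logical n-vector.
#' @export
high_confidence <- function(posterior, threshold = 0.1) {
  stopifnot(inherits(posterior, "ffc_posterior"))
  posterior$pep < threshold
}

#' @export
print.ffc_posterior <- function(x, ...) {
  cat("Forest fire Monte Carlo posterior\n")
  cat("  points:", nrow(x$counts), " clusters:", ncol(x$counts),
      " trials:", x$trials, " pep mode:", x$pep_mode, "\n")
  cat("  PEP quartiles:", paste(signif(stats::quantile(x$pep), 3),
                                collapse = " "), "\n")
  cat("  high-confidence (PEP < 0.1):", sum(x$pep < 0.1), "points\n")
  if (any(x$never_reached)) {
    cat("  never reached by any trial:", sum(x$never_reached), "points\n")
  }
  invisible(x)
}
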