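# Online (inductive) clustering: the fitted dataset is frozen training data;
# newly arrived points are assigned against it one at a time, and points no
# existing cluster can ignite seed brand-new clusters that propagate through
# the still-unlabeled newcomers only.

#' Joint affinity graph over training and new points
#'
#' Rebuilds the affinity graph on the concatenation of the training
#' coordinates and the new points, using the model's K and kernel
#' specification. Thresholds are recomputed on the joint graph by default
#' (the training points' local density changes slightly when newcomers land
#' nearby); `freeze_thresholds = TRUE` keeps the training thresholds from the
#' original fit instead.
#'
#' @param object A `forest_fire` fit made from a data matrix (so that the
#'   training coordinates are stored).
#' @param newdata Matrix of new points in the same coordinate space (same
#'   columns) as the training data; batch correction, shared-feature
#'   subsetting and projection into the training embedding are the caller's
#'   responsibility.
#' @param freeze_thresholds Keep training thresholds from the original graph.
#' @return An `ffc_graph` over the `n_train + n_test` points, with attribute
#'   `n_train`.
#' @export
joint_graph <- function(object, newdata, freeze_thresholds = FALSE) {
  stopifnot(inherits(object, "forest_fire"))
  if (is.null(object$data)) {
    stop("online assignment needs the training coordinates; fit forest_fire() ",
         "on a data matrix rather than a prebuilt graph")
  }
  train <- object$data
  n_train <- nrow(train)
  if (!is.null(newdata) && length(newdata)) {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != ncol(train)) {
      stop("dimension mismatch: training data has ", ncol(train),
           " columns but new data has ", ncol(newdata))
    }
    combined <- rbind(train, newdata)
  } else {
    combined <- train
  }
  spec <- object$graph$kernel
  g <- affinity_graph(combined, K = object$graph$K, kernel = spec$mode,
                      sigma = spec$sigma,
                      symmetrization = object$graph$symmetrization)
  if (freeze_thresholds) {
    g$threshold[seq_len(n_train)] <- object$graph$threshold
  }
  attr(g, "n_train") <- n_train
  g
}

#' Assign new points against a fitted Forest Fire clustering
#'
#' Works on the joint affinity graph in two phases. First, every new point is
#' visited in arrival order and offered to the existing clusters: the average
#' label influence from each labeled cluster is evaluated per the usual heat
#' rule, and the point takes the label of the highest influence among those
#' meeting its threshold (ties broken by the lowest cluster id). Points no
#' existing cluster can ignite are left unlabeled. Second, the leftovers are
#' visited in arrival order; each is re-offered to all clusters (including
#' clusters created meanwhile) and, if still unignitable, seeds a new cluster
#' — with an id strictly greater than every existing id — whose label then
#' propagates through the still-unlabeled new points only. Assigning before
#' any new-cluster fire is lit prevents a new label from burning through
#' not-yet-visited points that belong to existing clusters; training labels
#' never change.
#'
#' @param object A `forest_fire` fit holding its training coordinates.
#' @param newdata Matrix of new points (same columns as the training data).
#' @param order `"given"` (input order, default) or `"random"` (shuffled under
#'   `seed`). Arrival order matters when new clusters emerge.
#' @param seed RNG seed for the random arrival order.
#' @param freeze_thresholds See [joint_graph()].
#' @param ... Unused.
#' @return An object of class `ffc_online`: list with `test_labels` (integer
#'   labels for the rows of `newdata`), `new_cluster_seeds` (row indices of
#'   `newdata` that seeded new clusters), `influence` (n_test x k matrix of
#'   per-cluster average influence at assignment time, over the clusters that
#'   existed when each point arrived), `arrival` (the arrival order used) and
#'   `train_labels`.
#' @export
predict.forest_fire <- function(object, newdata, order = c("given", "random"),
                                seed = 0L, freeze_thresholds = FALSE, ...) {
  order <- match.arg(order)
  newdata <- as.matrix(newdata)
  n_test <- nrow(newdata)
  g <- joint_graph(object, newdata, freeze_thresholds = freeze_thresholds)
  n_train <- attr(g, "n_train")
  A <- g$affinity
  thr <- g$threshold
  labels <- c(object$labels, integer(n_test))
  arrival <- seq_len(n_test)
  if (order == "random") {
    arrival <- withr::with_seed(seed, sample(arrival))
  }
  max_id <- max(object$labels)
  influence <- matrix(NA_real_, n_test, max_id)
  new_seeds <- integer(0)
  test_mask <- c(rep(FALSE, n_train), rep(TRUE, n_test))

  # per-cluster average influence on joint vertex j from current labels
  cluster_influence <- function(j) {
    a <- A[, j]  # symmetric, so column = row
    labeled <- labels > 0L
    lab <- labels[labeled]
    sums <- rowsum(a[labeled], lab)            # per-cluster affinity sums
    ids <- as.integer(rownames(sums))
    sizes <- tabulate(lab)[ids]
    list(ids = ids, infl = object$temperature * sums[, 1] / sizes)
  }
  record <- function(i, ci) {
    if (ncol(influence) < max(ci$ids)) {
      influence <<- cbind(influence,
                          matrix(NA_real_, n_test,
                                 max(ci$ids) - ncol(influence)))
    }
    influence[i, ci$ids] <<- ci$infl
  }

  # phase 1: offer every arrival to the existing clusters
  for (i in arrival) {
    j <- n_train + i
    ci <- cluster_influence(j)
    record(i, ci)
    crossing <- ci$infl >= thr[j]
    if (any(crossing)) {
      # argmax influence among crossing clusters; ids ascending so a tie
      # resolves to the lowest cluster id
      labels[j] <- ci$ids[crossing][which.max(ci$infl[crossing])]
    }
  }
  # phase 2: leftovers seed new clusters that spread through new points only
  for (i in arrival) {
    j <- n_train + i
    if (labels[j] != 0L) next
    ci <- cluster_influence(j)
    record(i, ci)
    crossing <- ci$infl >= thr[j]
    if (any(crossing)) {
      labels[j] <- ci$ids[crossing][which.max(ci$infl[crossing])]
    } else {
      max_id <- max_id + 1L
      new_seeds <- c(new_seeds, i)
      res <- propagate(g, labels, j, max_id, object$temperature,
                       candidates = test_mask)
      labels <- res$labels
    }
  }
  structure(list(test_labels = labels[n_train + seq_len(n_test)],
                 new_cluster_seeds = new_seeds,
                 influence = influence,
                 arrival = arrival,
                 train_labels = object$labels),
            class = "ffc_online")
}

#' @export
print.ffc_online <- function(x, ...) {
  cat("Forest fire online assignment\n")
  cat("  new points:", length(x$test_labels),
      " new clusters seeded:", length(x$new_cluster_seeds), "\n")
  cat("  label table:\n")
  print(table(x$test_labels))
  invisible(x)
}
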