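# Readers and writers: dense CSV/TSV matrices, Matrix Market sparse matrices
# with barcode/feature sidecars, label/trace/posterior CSVs, and single-file
# JSON archives for graphs and online models. Cell identifiers are carried
# through every output and never silently permuted.

#' Read a cells x features matrix
#'
#' `csv`/`tsv`: expects a header row of feature names and a first column of
#' cell identifiers. `mtx`: a Matrix Market file in the conventional
#' genes x cells orientation with `barcodes.tsv` and `features.tsv` (or
#' `genes.tsv`) sidecars in the same directory; the result is transposed to
#' cells x features and kept sparse.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @return A numeric matrix (dense input) or `dgCMatrix` (MTX input) with
#'   dimnames.
#' @export
read_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension of ", path))
  }
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric values in ", path)
    rownames(m) <- as.character(df[[1L]])
    m
  } else {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    bc <- file.path(dir, "barcodes.tsv")
    ft_candidates <- file.path(dir, c("features.tsv", "genes.tsv"))
    ft <- ft_candidates[file.exists(ft_candidates)][1]
    if (file.exists(bc)) {
      barcodes <- readLines(bc)
      if (length(barcodes) != ncol(m)) {
        stop("barcodes.tsv has ", length(barcodes), " entries but the matrix ",
             "declares ", ncol(m), " columns (cells)")
      }
      colnames(m) <- barcodes
    }
    if (!is.na(ft)) {
      feats <- utils::read.table(ft, sep = "\t", stringsAsFactors = FALSE)
      if (nrow(feats) != nrow(m)) {
        stop(basename(ft), " has ", nrow(feats), " entries but the matrix ",
             "declares ", nrow(m), " rows (features)")
      }
      rownames(m) <- feats[[1L]]
    }
    methods::as(Matrix::t(m), "CsparseMatrix")  # cells x features
  }
}

#' Write a dense matrix with cell ids
#'
#' Companion writer to [read_matrix()] for CSV/TSV: first column `cell_id`,
#' then one column per feature.
#'
#' @param m Matrix with rownames (generated if absent).
#' @param path Output path; the extension decides the separator.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("cell", seq_len(nrow(m)))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.frame(cell_id = ids, m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

result_ids <- function(fit) {
  ids <- fit$graph$ids
  if (is.null(ids)) ids <- paste0("cell", seq_along(fit$labels))
  ids
}

#' Write cluster labels to CSV
#'
#' Columns `cell_id,label`, rows in input order.
#'
#' @param fit A `forest_fire` fit.
#' @param path Output path.
#' @export
write_labels <- function(fit, path) {
  stopifnot(inherits(fit, "forest_fire"))
  utils::write.csv(data.frame(cell_id = result_ids(fit), label = fit$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the heat trace to CSV
#'
#' Columns `order,cell_id,cluster,sweep,avg_heat`, one row per acceptance
#' event in acceptance order.
#'
#' @param fit A `forest_fire` fit.
#' @param path Output path.
#' @export
write_trace <- function(fit, path) {
  stopifnot(inherits(fit, "forest_fire"))
  tr <- fit$trace
  ids <- result_ids(fit)
  utils::write.csv(data.frame(order = tr$order, cell_id = ids[tr$vertex],
                              cluster = tr$cluster, sweep = tr$sweep,
                              avg_heat = tr$avg_heat),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write Monte Carlo posterior summaries to CSV
#'
#' Columns `cell_id,label,pep,entropy,received_trials`; optionally the wide
#' per-cluster counts matrix alongside, and a JSON metadata file recording
#' trials, PEP mode and master seed.
#'
#' @param posterior An `ffc_posterior`.
#' @param fit The `forest_fire` fit it validates (for cell ids).
#' @param path Output CSV path.
#' @param counts_path Optional path for the wide counts matrix.
#' @param meta_path Optional path for the JSON metadata block.
#' @export
write_posterior <- function(posterior, fit, path, counts_path = NULL,
                            meta_path = NULL) {
  stopifnot(inherits(posterior, "ffc_posterior"))
  ids <- result_ids(fit)
  utils::write.csv(data.frame(cell_id = ids, label = posterior$initial,
                              pep = posterior$pep, entropy = posterior$entropy,
                              received_trials = posterior$received),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(counts_path)) {
    cm <- posterior$counts
    colnames(cm) <- paste0("cluster", seq_len(ncol(cm)))
    utils::write.csv(data.frame(cell_id = ids, cm), counts_path,
                     row.names = FALSE, quote = FALSE)
  }
  if (!is.null(meta_path)) {
    jsonlite::write_json(list(trials = posterior$trials,
                              pep_mode = posterior$pep_mode,
                              master_seed = posterior$seed),
                         meta_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Serialize an affinity graph to a single JSON archive
#'
#' Stores the sparse affinity matrix as coordinate triplets together with the
#' degree and threshold vectors and a metadata block (K, kernel mode, sigma,
#' symmetrisation, package version).
#'
#' @param graph An `ffc_graph`.
#' @param path Output path.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "ffc_graph"))
  trip <- Matrix::summary(graph$affinity)
  obj <- list(meta = list(n = length(graph$degree), K = graph$K,
                          kernel = graph$kernel$mode,
                          sigma = graph$kernel$sigma,
                          symmetrization = graph$symmetrization,
                          version = as.character(utils::packageVersion("forestfire"))),
              i = trip$i, j = trip$j, x = trip$x,
              degree = graph$degree, threshold = graph$threshold,
              ids = graph$ids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an affinity graph archive written by [write_graph()]
#'
#' @param path Archive path.
#' @return An `ffc_graph`.
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- obj$meta$n
  A <- Matrix::sparseMatrix(i = obj$i, j = obj$j, x = obj$x, dims = c(n, n))
  structure(list(affinity = A, degree = obj$degree,
                 threshold = obj$threshold, K = obj$meta$K,
                 kernel = list(mode = obj$meta$kernel,
                               sigma = obj$meta$sigma),
                 symmetrization = obj$meta$symmetrization,
                 ids = if (length(obj$ids)) obj$ids),
            class = "ffc_graph")
}

#' Save a fitted model for later online assignment
#'
#' Stores the training coordinates, labels and clustering parameters in one
#' JSON archive; [read_model()] restores an object usable with
#' [predict.forest_fire()].
#'
#' @param fit A `forest_fire` fit made from a data matrix.
#' @param path Output path.
#' @export
write_model <- function(fit, path) {
  stopifnot(inherits(fit, "forest_fire"))
  if (is.null(fit$data)) stop("the fit holds no training coordinates")
  obj <- list(meta = list(temperature = fit$temperature, K = fit$graph$K,
                          kernel = fit$graph$kernel$mode,
                          sigma = fit$graph$kernel$sigma,
                          symmetrization = fit$graph$symmetrization,
                          version = as.character(utils::packageVersion("forestfire"))),
              data = fit$data, labels = fit$labels,
              ids = fit$graph$ids)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model archive written by [write_model()]
#'
#' Rebuilds the affinity graph from the stored coordinates and parameters, so
#' the restored object supports [predict.forest_fire()] and [mc_validate()].
#'
#' @param path Archive path.
#' @return A `forest_fire` object.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  data <- as.matrix(obj$data)
  if (length(obj$ids)) rownames(data) <- obj$ids
  graph <- affinity_graph(data, K = obj$meta$K, kernel = obj$meta$kernel,
                          sigma = obj$meta$sigma,
                          symmetrization = obj$meta$symmetrization)
  labels <- as.integer(obj$labels)
  structure(list(labels = labels, k = max(labels),
                 seeds = integer(0), trace = NULL,
                 temperature = obj$meta$temperature, graph = graph,
                 data = data, call = NULL),
            class = "forest_fire")
}
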