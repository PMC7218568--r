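#' Depth-normalize a fragment count matrix
#'
#' Rescales each cell to a common depth of 10,000 fragments and applies a
#' log2 transform:
#' \deqn{B'_{ij} = \log_2\left(\frac{B_{ij} \cdot 10000}{\sum_{j'} B_{ij'}} + 1\right)}
#' Zero entries stay exactly zero, so sparsity is preserved, and all-zero
#' cells map to all-zero rows (no division by zero).
#'
#' @param x a [fragment_matrix()] or sparse cells-by-peaks count matrix.
#' @param scale target per-cell depth (default 10000).
#' @return sparse cells-by-peaks dgCMatrix of normalized values.
#' @export
normalize_counts <- function(x, scale = 10000) {
  counts <- if (inherits(x, "fragment_matrix")) x$counts else
    as(as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  rs <- Matrix::rowSums(counts)
  tm <- as(counts, "TsparseMatrix")
  denom <- rs[tm@i + 1L]
  tm@x <- log2(tm@x * scale / ifelse(denom > 0, denom, 1) + 1)
  as(tm, "CsparseMatrix")
}

#' Embed peaks in principal-component space
#'
#' Computes an exact truncated SVD of the column-centered normalized
#' matrix (cells-by-peaks; each peak column is centered, columns are not
#' scaled) and places each peak at its loading scaled by the singular
#' value, so Euclidean distances between peaks reflect the covariance of
#' their accessibility patterns across cells. Component signs are fixed by
#' requiring the largest-magnitude loading of each component to be
#' positive, making the embedding deterministic.
#'
#' @param norm normalized matrix from [normalize_counts()].
#' @param n_pcs number of components to keep (default 40); clipped with a
#'   warning if it exceeds `min(dim(norm))`.
#' @return An object of class `peak_embedding`: list with `coords`
#'   (peaks x n_pcs), `n_pcs`, `var_fraction` (fraction of total variance
#'   per kept component), and `basis` (cell-side singular vectors, used
#'   for reconstruction checks).
#' @export
embed_peaks <- function(norm, n_pcs = 40) {
  if (n_pcs < 1) stop("n_pcs must be >= 1")
  x <- as.matrix(norm)
  k_max <- min(dim(x))
  if (n_pcs > k_max) {
    warning("n_pcs clipped from ", n_pcs, " to ", k_max)
    n_pcs <- k_max
  }
  xc <- sweep(x, 2, colMeans(x))
  s <- svd(xc)
  # deterministic sign: largest-magnitude loading of each component positive
  for (c in seq_len(n_pcs)) {
    j <- which.max(abs(s$v[, c]))
    if (s$v[j, c] < 0) {
      s$v[, c] <- -s$v[, c]
      s$u[, c] <- -s$u[, c]
    }
  }
  tot <- sum(s$d^2)
  coords <- sweep(s$v[, seq_len(n_pcs), drop = FALSE], 2,
                  s$d[seq_len(n_pcs)], `*`)
  rownames(coords) <- colnames(norm)
  structure(list(coords = coords, n_pcs = n_pcs,
                 var_fraction = if (tot > 0) s$d[seq_len(n_pcs)]^2 / tot
                                else rep(0, n_pcs),
                 basis = s$u[, seq_len(n_pcs), drop = FALSE]),
            class = "peak_embedding")
}

# symmetric (union) k-nearest-neighbor graph on the rows of `coords`;
# Euclidean metric, ties at the k-th distance broken by lower row index,
# self excluded, zero diagonal. Returns a binary sparse adjacency matrix.
knn_adjacency <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) stop("k (", k, ") must be smaller than the number of points (",
                   n, ")")
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  # order() is stable, so equidistant neighbors resolve to lower indices
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn))
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  a <- a + Matrix::t(a)
  a@x[] <- 1
  a
}

#' Build the peak connectivity graph
#'
#' K-nearest-neighbor graph of peaks in principal-component space
#' (Euclidean metric), symmetrized by union. This is the connectivity
#' matrix that constrains which peaks may be merged into a common
#' accesson.
#'
#' @param embedding a [embed_peaks()] result.
#' @param k neighbors per peak (default 10).
#' @return An object of class `peak_graph`: list with sparse symmetric
#'   binary `adjacency` and `k`.
#' @export
build_peak_graph <- function(embedding, k = 10) {
  stopifnot(inherits(embedding, "peak_embedding"))
  structure(list(adjacency = knn_adjacency(embedding$coords, k), k = k),
            class = "peak_graph")
}

# 2-column, 0-based unique undirected edge list of a symmetric adjacency
adjacency_edges <- function(adjacency) {
  tm <- as(as(adjacency, "TsparseMatrix"), "generalMatrix")
  keep <- tm@i < tm@j
  cbind(tm@i[keep], tm@j[keep])
}

#' Group peaks into accessons
#'
#' Connectivity-constrained agglomerative clustering of peaks: starting
#' from singletons, the pair of clusters joined by at least one edge of
#' the peak graph whose merge least increases the within-cluster sum of
#' squares (Ward criterion, Euclidean metric in PC space) is merged, until
#' `n_accessons` clusters remain. If the graph decomposes into more than
#' `n_accessons` connected components, the components themselves are
#' returned as accessons with a warning.
#'
#' @param embedding a [embed_peaks()] result.
#' @param graph a [build_peak_graph()] result.
#' @param n_accessons target number of accessons (default 600).
#' @return An object of class `accesson_assignment`: list with `labels`
#'   (per-peak accesson id, dense 1..n) and `n_accessons`.
#' @export
group_peaks <- function(embedding, graph, n_accessons = 600) {
  stopifnot(inherits(embedding, "peak_embedding"),
            inherits(graph, "peak_graph"))
  n <- nrow(embedding$coords)
  if (n_accessons < 1 || n_accessons > n)
    stop("n_accessons must lie in [1, ", n, "]")
  edges <- adjacency_edges(graph$adjacency)
  labels <- .ward_constrained_cpp(embedding$coords,
                                  matrix(as.integer(edges), ncol = 2),
                                  as.integer(n_accessons))
  got <- attr(labels, "n_groups")
  if (got > n_accessons)
    warning("peak graph has ", got, " connected components; returning ",
            got, " accessons instead of the requested ", n_accessons)
  structure(list(labels = as.integer(labels), n_accessons = got),
            class = "accesson_assignment")
}

#' @exportS3Method base::print
print.accesson_assignment <- function(x, ...) {
  sizes <- tabulate(x$labels, x$n_accessons)
  cat("accesson_assignment:", length(x$labels), "peaks in", x$n_accessons,
      "accessons\n")
  cat("  peaks per accesson: min", min(sizes), "/ median", median(sizes),
      "/ max", max(sizes), "\n")
  invisible(x)
}

#' Build the cell-by-accesson matrix
#'
#' Sums the raw fragment counts of all peaks in each accesson per cell
#' (so each cell's accesson row sum equals its total peak count exactly)
#' and row-normalizes the result either to z-scores (population SD;
#' constant rows map to zeros) or probabilities (rows sum to 1; all-zero
#' rows stay zero).
#'
#' @param x a [fragment_matrix()] or cells-by-peaks count matrix.
#' @param assignment an [group_peaks()] result covering all peaks of `x`.
#' @param method `"zscore"` (default) or `"probability"`.
#' @return An object of class `accesson_matrix`: list with `raw`
#'   (cells x accessons, dense), `normalized` (same shape), and `method`.
#' @export
build_accesson_matrix <- function(x, assignment,
                                  method = c("zscore", "probability")) {
  method <- match.arg(method)
  counts <- if (inherits(x, "fragment_matrix")) x$counts else x
  stopifnot(inherits(assignment, "accesson_assignment"))
  if (length(assignment$labels) != ncol(counts))
    stop("assignment covers ", length(assignment$labels),
         " peaks but the matrix has ", ncol(counts))
  ind <- Matrix::sparseMatrix(i = seq_along(assignment$labels),
                              j = assignment$labels, x = 1,
                              dims = c(ncol(counts), assignment$n_accessons))
  raw <- as.matrix(counts %*% ind)
  rownames(raw) <- rownames(counts)
  colnames(raw) <- paste0("acc", seq_len(assignment$n_accessons))
  normalized <- switch(method,
                       zscore = .zscore_rows(raw),
                       probability = .prob_rows(raw))
  structure(list(raw = raw, normalized = normalized, method = method),
            class = "accesson_matrix")
}

#' @exportS3Method base::print
print.accesson_matrix <- function(x, ...) {
  cat("accesson_matrix:", nrow(x$raw), "cells x", ncol(x$raw),
      "accessons (", x$method, "normalized )\n")
  invisible(x)
}
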