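#' Build the cell connectivity graph
#'
#' Euclidean k-nearest-neighbor graph on the rows of the normalized
#' accesson matrix, symmetrized by union, self excluded.
#'
#' @param M an [build_accesson_matrix()] result or a plain
#'   cells-by-features matrix (rows are used as coordinates).
#' @param n_neighbors neighbors per cell (default 20); must be smaller
#'   than the number of cells.
#' @return An object of class `cell_graph`: list with sparse symmetric
#'   binary `adjacency`, `n_neighbors`, and the `coords` used.
#' @export
build_cell_graph <- function(M, n_neighbors = 20) {
  coords <- if (inherits(M, "accesson_matrix")) M$normalized else as.matrix(M)
  adjacency <- knn_adjacency(coords, n_neighbors)
  structure(list(adjacency = adjacency, n_neighbors = n_neighbors,
                 coords = coords),
            class = "cell_graph")
}

#' Cluster cells by Louvain community detection
#'
#' Modularity-based community detection on the cell graph; the number of
#' clusters is chosen automatically by the algorithm. Labels are
#' relabeled densely in order of decreasing cluster size. A graph with no
#' edges yields one singleton cluster per cell with a warning.
#'
#' @param graph a [build_cell_graph()] result.
#' @param resolution Louvain resolution parameter (default 1.0).
#' @param seed integer seed; required for reproducible community assignment.
#' @return integer vector of cluster ids (1..k), one per cell, with
#'   attribute `"n_clusters"`.
#' @export
louvain_cluster <- function(graph, resolution = 1.0, seed = 1) {
  stopifnot(inherits(graph, "cell_graph"))
  adj <- graph$adjacency
  n <- nrow(adj)
  if (length(adj@x) == 0) {
    warning("cell graph has no edges; every cell becomes a singleton cluster")
    labels <- seq_len(n)
    attr(labels, "n_clusters") <- n
    return(labels)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  relabel_by_size(as.integer(igraph::membership(comm)))
}

# dense 1..k ids ordered by decreasing cluster size (ties: lower old id)
relabel_by_size <- function(labels) {
  sizes <- table(labels)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  out <- match(labels, as.integer(names(sizes))[ord])
  attr(out, "n_clusters") <- length(sizes)
  out
}

#' Cluster cells into a fixed number of groups
#'
#' Connectivity-constrained agglomerative clustering of cells (Ward
#' criterion, Euclidean metric on the normalized accesson rows), with
#' merges restricted to edges of the cell graph — the fixed-cluster-count
#' alternative to [louvain_cluster()] when the user wants to set the
#' number of clusters.
#'
#' @param graph a [build_cell_graph()] result.
#' @param n_clusters number of clusters to produce.
#' @return integer vector of cluster ids with attribute `"n_clusters"`.
#' @export
knn_cluster <- function(graph, n_clusters) {
  stopifnot(inherits(graph, "cell_graph"))
  n <- nrow(graph$coords)
  if (n_clusters < 1 || n_clusters > n)
    stop("n_clusters must lie in [1, ", n, "]")
  edges <- adjacency_edges(graph$adjacency)
  labels <- .ward_constrained_cpp(graph$coords,
                                  matrix(as.integer(edges), ncol = 2),
                                  as.integer(n_clusters))
  got <- attr(labels, "n_groups")
  if (got > n_clusters)
    warning("cell graph has ", got, " connected components; returning ",
            got, " clusters instead of the requested ", n_clusters)
  out <- as.integer(labels)
  attr(out, "n_clusters") <- got
  out
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between a reference partition and a
#' predicted partition, computed from the contingency table
#' \eqn{n_{ij}} with row sums \eqn{a_i}, column sums \eqn{b_j} and total
#' \eqn{n}:
#' \deqn{\mathrm{ARI} = \frac{\sum_{ij}\binom{n_{ij}}{2} -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}
#'   {[\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}]/2 -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}}
#' Cells whose reference label is the reserved `"unknown"` category (or
#' `NA`) are excluded before computing, so unassignable reference cells do
#' not penalize the score. ARI is 1 for identical partitions (up to
#' relabeling) and has expectation ~0 for independent random partitions.
#'
#' @param truth reference labels (any atomic type).
#' @param pred predicted labels, same length.
#' @param ignore_unknown drop cells with unknown truth (default TRUE).
#' @param unknown_label value(s) of `truth` treated as unknown.
#' @return a single numeric value in \[-1, 1\].
#' @export
adjusted_rand_index <- function(truth, pred, ignore_unknown = TRUE,
                                unknown_label = "unknown") {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  keep <- if (ignore_unknown) !(truth %in% unknown_label) & !is.na(truth)
          else rep(TRUE, length(truth))
  t_lab <- truth[keep]
  p_lab <- pred[keep]
  if (length(t_lab) < 2)
    stop("fewer than 2 usable cells after removing unknowns; ARI undefined")
  tab <- table(t_lab, p_lab)
  n <- sum(tab)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  expected <- s_a * s_b / choose(n, 2)
  denom <- (s_a + s_b) / 2 - expected
  if (denom == 0) return(1) # both partitions trivial and identical in pairs
  (s_ij - expected) / denom
}

#' Cell-cell correlation matrix with dendrogram ordering
#'
#' Pearson correlation between the normalized accesson rows of all cell
#' pairs, together with the leaf order of average-linkage hierarchical
#' clustering of `1 - correlation`, for heatmap display of cluster
#' structure. Constant rows have undefined correlations; these are set to
#' 0 with a warning.
#'
#' @param M an [build_accesson_matrix()] result or cells-by-features matrix.
#' @return An object of class `cell_correlation`: list with `correlation`
#'   (cells x cells), `order` (dendrogram leaf order), and `hclust`.
#' @export
cell_correlation_matrix <- function(M) {
  x <- if (inherits(M, "accesson_matrix")) M$normalized else as.matrix(M)
  if (nrow(x) < 2) stop("need at least 2 cells")
  sds <- apply(x, 1, sd)
  cc <- suppressWarnings(cor(t(x)))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant cell row(s); correlations set to 0")
    cc[is.na(cc)] <- 0
  }
  diag(cc) <- 1
  hc <- hclust(as.dist(1 - cc), method = "average")
  structure(list(correlation = cc, order = hc$order, hclust = hc),
            class = "cell_correlation")
}

#' @exportS3Method base::print
print.cell_correlation <- function(x, ...) {
  cat("cell_correlation:", nrow(x$correlation), "cells, off-diagonal range [",
      sprintf("%.3f", min(x$correlation[lower.tri(x$correlation)])), ",",
      sprintf("%.3f", max(x$correlation[lower.tri(x$correlation)])), "]\n")
  invisible(x)
}
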