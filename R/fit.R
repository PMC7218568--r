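#' Fit the accesson model and cluster cells
#'
#' The package's main entry point. Runs the full estimator on a fragment
#' count matrix:
#' 1. depth normalization, \eqn{B'_{ij} = \log_2(B_{ij} \cdot 10^4 /
#'    \sum_{j'} B_{ij'} + 1)} ([normalize_counts()]);
#' 2. peak embedding in the top `n_pcs` principal components
#'    ([embed_peaks()]) and a `peak_knn`-nearest-neighbor peak graph
#'    ([build_peak_graph()]);
#' 3. accesson construction by connectivity-constrained Ward clustering
#'    into `n_accessons` groups ([group_peaks()]);
#' 4. the cell-by-accesson matrix with per-cell z-score or probability
#'    normalization ([build_accesson_matrix()]);
#' 5. a `cell_knn`-nearest-neighbor cell graph ([build_cell_graph()]) and
#'    Louvain community detection ([louvain_cluster()]), or — when
#'    `n_clusters` is given — connectivity-constrained Ward clustering of
#'    cells into that many groups ([knn_cluster()]).
#'
#' `n_accessons` larger than the number of peaks is capped at the number
#' of peaks with a warning.
#'
#' @param x a [fragment_matrix()] or sparse cells-by-peaks count matrix.
#' @param n_accessons number of accessons (default 600; the useful range
#'   is roughly 500-1500 and results are stable across it).
#' @param peak_knn neighbors in the peak graph (default 10).
#' @param n_pcs principal components for the peak embedding (default 40).
#' @param norm accesson-matrix row normalization, `"zscore"` (default) or
#'   `"probability"`.
#' @param cell_knn neighbors in the cell graph (default 20).
#' @param resolution Louvain resolution (default 1.0).
#' @param n_clusters optional fixed cluster count; switches cell
#'   clustering from Louvain to constrained Ward.
#' @param seed integer seed controlling the community detection (default 1).
#' @return An object of class `accesson_fit`: list with `data` (the
#'   input), `normalized`, `embedding`, `graph`, `assignment`, `M`
#'   (accesson matrix), `cell_graph`, `cluster` (per-cell integer
#'   labels), `n_clusters`, and `params`.
#' @examples
#' sim <- generate_dataset(synthetic_config(seed = 7))
#' fit <- accesson_fit(sim$data, seed = 7)
#' fit
#' adjusted_rand_index(sim$truth$cell_type, fit$cluster)
#' @export
accesson_fit <- function(x, n_accessons = 600, peak_knn = 10, n_pcs = 40,
                         norm = c("zscore", "probability"), cell_knn = 20,
                         resolution = 1.0, n_clusters = NULL, seed = 1) {
  norm <- match.arg(norm)
  if (!inherits(x, "fragment_matrix") && is.null(dim(x)))
    stop("x must be a fragment_matrix or a cells-by-peaks matrix")
  counts <- if (inherits(x, "fragment_matrix")) x$counts else x
  n_peaks <- ncol(counts)
  if (n_accessons > n_peaks) {
    warning("n_accessons capped at the number of peaks (", n_peaks, ")")
    n_accessons <- n_peaks
  }
  normalized <- normalize_counts(counts)
  embedding <- embed_peaks(normalized, n_pcs = n_pcs)
  graph <- build_peak_graph(embedding, k = peak_knn)
  assignment <- group_peaks(embedding, graph, n_accessons = n_accessons)
  M <- build_accesson_matrix(counts, assignment, method = norm)
  cell_graph <- build_cell_graph(M, n_neighbors = cell_knn)
  cluster <- if (is.null(n_clusters))
    louvain_cluster(cell_graph, resolution = resolution, seed = seed)
  else
    knn_cluster(cell_graph, n_clusters = n_clusters)
  structure(list(data = x, normalized = normalized, embedding = embedding,
                 graph = graph, assignment = assignment, M = M,
                 cell_graph = cell_graph, cluster = as.integer(cluster),
                 n_clusters = attr(cluster, "n_clusters"),
                 params = list(n_accessons = n_accessons,
                               peak_knn = peak_knn, n_pcs = n_pcs,
                               norm = norm, cell_knn = cell_knn,
                               resolution = resolution,
                               n_clusters = n_clusters, seed = seed)),
            class = "accesson_fit")
}

#' @exportS3Method base::print
print.accesson_fit <- function(x, ...) {
  cat("accesson_fit\n")
  cat("  ", nrow(x$M$raw), " cells, ", length(x$assignment$labels),
      " peaks, ", x$assignment$n_accessons, " accessons (",
      x$M$method, " normalized)\n", sep = "")
  cat("  ", x$n_clusters, " cell clusters:\n", sep = "")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' @exportS3Method base::summary
summary.accesson_fit <- function(object, ...) {
  acc_sizes <- tabulate(object$assignment$labels,
                        object$assignment$n_accessons)
  structure(list(n_cells = nrow(object$M$raw),
                 n_peaks = length(object$assignment$labels),
                 n_accessons = object$assignment$n_accessons,
                 accesson_size_quartiles = quantile(acc_sizes),
                 n_clusters = object$n_clusters,
                 cluster_sizes = table(object$cluster),
                 params = object$params),
            class = "summary.accesson_fit")
}

#' @exportS3Method base::print
print.summary.accesson_fit <- function(x, ...) {
  cat("accesson model summary\n")
  cat("  cells:", x$n_cells, " peaks:", x$n_peaks, "\n")
  cat("  accessons:", x$n_accessons, "- peaks per accesson (quartiles):",
      paste(x$accesson_size_quartiles, collapse = " / "), "\n")
  cat("  clusters:", x$n_clusters, "\n")
  print(x$cluster_sizes)
  cat("  parameters: n_accessons =", x$params$n_accessons,
      ", peak_knn =", x$params$peak_knn, ", n_pcs =", x$params$n_pcs,
      ", norm =", x$params$norm, ", cell_knn =", x$params$cell_knn,
      ", resolution =", x$params$resolution, "\n")
  invisible(x)
}

#' Plot an accesson model fit
#'
#' Scatter of the cells in the first two principal components of the
#' accesson matrix, colored by cluster.
#'
#' @param x an [accesson_fit()] result.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the [accesson_pca()] embedding that was plotted.
#' @exportS3Method base::plot
plot.accesson_fit <- function(x, ...) {
  emb <- accesson_pca(x$M, n_pcs = 2)
  cols <- hcl.colors(max(x$cluster), "Dark 3")
  plot(emb$coords[, 1], emb$coords[, 2], col = cols[x$cluster], pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", 100 * emb$var_fraction[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * emb$var_fraction[2]), ...)
  legend("topright", legend = paste("cluster", seq_len(max(x$cluster))),
         col = cols, pch = 19, cex = 0.8)
  invisible(emb)
}
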