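#' Low-dimensional cell embedding of the accesson matrix
#'
#' PCA of cells over accesson columns — the feature matrix handed to
#' external pseudotime engines (Monocle, SPRING and kin). By default the
#' probability-normalized accesson matrix is decomposed; the raw summed
#' counts can be used instead. Each component's Pearson correlation with
#' per-cell sequencing depth is reported, and the single component most
#' confounded with depth (|r| > 0.8) can optionally be dropped and
#' replaced by the next one, since a depth component carries no lineage
#' information.
#'
#' @param M an [build_accesson_matrix()] result (or a plain
#'   cells-by-accessons matrix, in which case `depth` defaults to its row
#'   sums).
#' @param n_pcs number of components to return (default 5, >= 2).
#' @param use `"probability"` (default) or `"raw"` accesson values.
#' @param drop_depth_pc drop the first component whose absolute depth
#'   correlation exceeds 0.8, if any (default FALSE).
#' @return An object of class `cell_embedding`: list with `coords`
#'   (cells x n_pcs), `var_fraction`, and `depth_correlation` (one value
#'   per returned component).
#' @export
accesson_pca <- function(M, n_pcs = 5, use = c("probability", "raw"),
                         drop_depth_pc = FALSE) {
  use <- match.arg(use)
  if (n_pcs < 2) stop("n_pcs must be >= 2")
  if (inherits(M, "accesson_matrix")) {
    raw <- M$raw
    x <- switch(use, probability = .prob_rows(raw), raw = raw)
    depth <- rowSums(raw)
  } else {
    x <- as.matrix(M)
    depth <- rowSums(x)
  }
  k_extra <- if (drop_depth_pc) 1 else 0
  k <- min(n_pcs + k_extra, dim(x))
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  coords <- pc$x
  var_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  dcor <- apply(coords, 2, function(v)
    if (sd(v) > 0 && sd(depth) > 0) cor(v, depth) else 0)
  keep <- seq_len(min(n_pcs, ncol(coords)))
  if (drop_depth_pc) {
    confounded <- which(abs(dcor) > 0.8)
    if (length(confounded) > 0) {
      drop <- confounded[1]
      keep <- setdiff(seq_len(ncol(coords)), drop)[seq_len(
        min(n_pcs, ncol(coords) - 1))]
    }
  }
  structure(list(coords = coords[, keep, drop = FALSE],
                 var_fraction = var_fraction[keep],
                 depth_correlation = dcor[keep]),
            class = "cell_embedding")
}

#' @exportS3Method base::print
print.cell_embedding <- function(x, ...) {
  cat("cell_embedding:", nrow(x$coords), "cells x", ncol(x$coords),
      "components\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$var_fraction), collapse = " "), "\n")
  cat("  depth correlations:",
      paste(sprintf("%+.2f", x$depth_correlation), collapse = " "), "\n")
  invisible(x)
}

#' Binned score curves along a pseudotime ordering
#'
#' Cells of each branch are sorted by pseudotime and split into
#' `n_bins` equal-count bins; each bin contributes its mean pseudotime
#' (bin center), mean score, and standard error. Branches with fewer
#' cells than bins get correspondingly fewer bins (with a warning);
#' branches with fewer than 2 cells are skipped with a warning. Because
#' binning depends only on the ordering, curves are invariant under any
#' order-preserving reparameterization of pseudotime.
#'
#' @param values per-cell score vector, or cells-by-scores matrix.
#' @param pseudotime per-cell finite numeric pseudotime.
#' @param branch optional per-cell branch id (default: one branch).
#' @param n_bins number of equal-count bins per branch (default 20).
#' @return data.frame with columns `branch`, `score`, `bin`,
#'   `pseudotime` (bin center), `mean`, `se`, `n`.
#' @export
score_along_pseudotime <- function(values, pseudotime, branch = NULL,
                                   n_bins = 20) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("score", seq_len(ncol(values)))
  if (length(pseudotime) != nrow(values))
    stop("need one pseudotime per cell")
  if (any(!is.finite(pseudotime))) stop("pseudotime must be finite")
  if (is.null(branch)) branch <- rep("branch1", nrow(values))
  out <- list()
  for (b in unique(branch)) {
    idx <- which(branch == b)
    if (length(idx) < 2) {
      warning("branch '", b, "' has fewer than 2 cells; skipped")
      next
    }
    nb <- n_bins
    if (length(idx) < n_bins) {
      warning("branch '", b, "' has ", length(idx), " cells; using ",
              length(idx), " bins")
      nb <- length(idx)
    }
    ord <- idx[order(pseudotime[idx])]
    bin <- ceiling(seq_along(ord) / (length(ord) / nb))
    bin <- pmin(bin, nb)
    for (s in colnames(values)) {
      agg_m <- tapply(values[ord, s], bin, mean)
      agg_sd <- tapply(values[ord, s], bin, sd)
      agg_n <- tapply(values[ord, s], bin, length)
      agg_t <- tapply(pseudotime[ord], bin, mean)
      out[[length(out) + 1]] <- data.frame(
        branch = b, score = s, bin = as.integer(names(agg_m)),
        pseudotime = as.numeric(agg_t), mean = as.numeric(agg_m),
        se = ifelse(agg_n > 1, agg_sd / sqrt(agg_n), 0),
        n = as.integer(agg_n), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no branch with >= 2 cells")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
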