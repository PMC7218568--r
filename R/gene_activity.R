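#' Read a gene TSS table
#'
#' @param path TSV with columns `gene chrom tss strand` (header optional;
#'   detected from the first line).
#' @return data.frame with those four columns.
#' @export
read_tss <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("gene", strsplit(first, "\t")[[1]][1], ignore.case = TRUE)
  tss <- read.table(path, sep = "\t", header = has_header,
                    stringsAsFactors = FALSE)
  if (!has_header) names(tss)[1:4] <- c("gene", "chrom", "tss", "strand")
  validate_tss(tss)
}

validate_tss <- function(tss) {
  tss <- as.data.frame(tss)
  need <- c("gene", "chrom", "tss")
  if (!all(need %in% names(tss)))
    stop("TSS table needs columns gene, chrom, tss")
  if (!"strand" %in% names(tss)) tss$strand <- "+"
  tss$gene <- as.character(tss$gene)
  tss$chrom <- as.character(tss$chrom)
  tss$tss <- as.numeric(tss$tss)
  if (any(tss$tss < 0)) stop("TSS positions must be >= 0")
  if (anyDuplicated(tss[c("gene", "tss")]))
    stop("duplicate (gene, tss) rows in TSS table")
  tss[c("gene", "chrom", "tss", "strand")]
}

#' Map peaks to genes through TSS windows
#'
#' A peak belongs to a gene when its half-open interval intersects the
#' half-open window `[tss - window, tss + window)` on the same chromosome.
#' One peak may map to several genes; genes without any peak in their
#' window keep an empty entry.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`) or a
#'   [fragment_matrix()].
#' @param tss TSS table, see [read_tss()].
#' @param window half-width of the TSS window in bp (default 20000).
#' @return named list mapping each gene to an integer vector of peak
#'   (column) indices.
#' @export
map_peaks_to_genes <- function(peaks, tss, window = 20000) {
  if (window <= 0) stop("window must be > 0")
  if (inherits(peaks, "fragment_matrix")) peaks <- peaks$peaks
  peaks <- validate_peaks(peaks)
  tss <- validate_tss(tss)
  pk <- GenomicRanges::GRanges(peaks$chrom,
          IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  win <- GenomicRanges::GRanges(tss$chrom,
          IRanges::IRanges(start = pmax(tss$tss - window, 0) + 1,
                           end = tss$tss + window))
  # suppress the informational seqlevels notice when chromosome sets differ
  hits <- suppressWarnings(GenomicRanges::findOverlaps(win, pk))
  map <- split(S4Vectors::subjectHits(hits),
               tss$gene[S4Vectors::queryHits(hits)])
  out <- setNames(vector("list", nrow(tss)), tss$gene)
  out[] <- list(integer(0))
  out[names(map)] <- lapply(map, function(i) sort(unique(as.integer(i))))
  if (all(lengths(out) == 0))
    warning("no peak intersects any TSS window")
  out
}

#' Gene activity scores from peak counts
#'
#' The raw score of gene *j* in cell *i* is the mean raw fragment count
#' over the peaks mapped to *j*. When `normalize` is TRUE each gene
#' column is rescaled to sum to 10,000 over cells
#' (\eqn{S'_{ij} = S_{ij} \cdot 10000 / \sum_i S_{ij}}), bringing the
#' scores onto a scale comparable to depth-normalized gene expression.
#' Genes with no mapped peaks have all-zero columns before and after
#' normalization.
#'
#' @param x a [fragment_matrix()] or cells-by-peaks count matrix.
#' @param map gene-to-peak map from [map_peaks_to_genes()].
#' @param normalize apply the per-gene column normalization (default TRUE).
#' @return An object of class `gene_scores`: list with `raw` and
#'   `normalized` (cells x genes matrices; `normalized` is NULL when
#'   `normalize = FALSE`).
#' @export
gene_scores <- function(x, map, normalize = TRUE) {
  counts <- if (inherits(x, "fragment_matrix")) x$counts else x
  if (length(map) == 0) stop("empty gene map")
  n_peaks_per_gene <- lengths(map)
  j <- rep(seq_along(map), n_peaks_per_gene)
  i <- unlist(map, use.names = FALSE)
  if (length(i) > 0 && max(i) > ncol(counts))
    stop("gene map references peak indices beyond the matrix")
  w <- Matrix::sparseMatrix(i = i, j = j,
                            x = 1 / n_peaks_per_gene[j],
                            dims = c(ncol(counts), length(map)))
  raw <- as.matrix(counts %*% w)
  dimnames(raw) <- list(rownames(counts), names(map))
  normalized <- NULL
  if (normalize) {
    cs <- colSums(raw)
    normalized <- sweep(raw, 2, ifelse(cs > 0, cs, 1), `/`) * 10000
    normalized[, cs == 0] <- 0
  }
  structure(list(raw = raw, normalized = normalized), class = "gene_scores")
}

# vectorized two-sided Welch t-test of group-1 columns vs group-2 columns,
# computed with centered sums for numerical stability; returns statistic,
# df, p. Degenerate columns (zero pooled standard error) get stat 0, p 1.
welch_test <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(se2 > 0, 2 * pt(abs(stat), df, lower.tail = FALSE), 1)
  list(statistic = stat, df = df, p_value = p,
       mean_target = m1, mean_rest = m2)
}

#' Differential features between one cluster and the rest
#'
#' Per feature (gene score or accesson column), a two-sided Welch t-test
#' of the target cluster against all other cells, a fold change
#' \eqn{(\bar x_{target} + \epsilon)/(\bar x_{rest} + \epsilon)} with
#' pseudocount \eqn{\epsilon} to guard sparse zero means, and
#' Benjamini-Hochberg adjustment across features. A feature passes when
#' the adjusted p-value is at most `p_cutoff` and the fold change at
#' least `fc_cutoff`.
#'
#' @param scores a [gene_scores()] result (its `normalized` slot is
#'   tested), an [build_accesson_matrix()] result (its probability-scale
#'   values are tested), or a plain cells-by-features matrix.
#' @param labels per-cell cluster labels.
#' @param target_cluster the cluster to contrast against the rest.
#' @param p_cutoff adjusted p-value cutoff (default 0.05).
#' @param fc_cutoff fold-change cutoff (default 2.0).
#' @param eps fold-change pseudocount (default 0.01).
#' @return data.frame with one row per feature: `feature`, `statistic`,
#'   `p_value`, `p_adjusted`, `fold_change`, `pass`.
#' @export
differential_features <- function(scores, labels, target_cluster,
                                  p_cutoff = 0.05, fc_cutoff = 2.0,
                                  eps = 0.01) {
  x <- if (inherits(scores, "gene_scores")) {
    if (is.null(scores$normalized)) scores$raw else scores$normalized
  } else if (inherits(scores, "accesson_matrix")) {
    .prob_rows(scores$raw)
  } else as.matrix(scores)
  if (length(labels) != nrow(x))
    stop("need one label per cell")
  in_target <- labels == target_cluster
  if (sum(in_target) < 3)
    stop("cluster '", target_cluster, "' has fewer than 3 cells")
  if (sum(!in_target) < 3)
    stop("complement of cluster '", target_cluster,
         "' has fewer than 3 cells")
  wt <- welch_test(x[in_target, , drop = FALSE], x[!in_target, , drop = FALSE])
  fc <- (wt$mean_target + eps) / (wt$mean_rest + eps)
  padj <- p.adjust(wt$p_value, method = "BH")
  data.frame(feature = colnames(x) %||% paste0("f", seq_len(ncol(x))),
             statistic = wt$statistic, p_value = wt$p_value,
             p_adjusted = padj, fold_change = fc,
             pass = padj <= p_cutoff & fc >= fc_cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname differential_features
#' @export
differential_genes <- differential_features

#' Differential genes through differential accessons
#'
#' The sparse-data pathway: differential accessons between the target
#' cluster and the rest are found first (same Welch test / fold-change /
#' BH procedure on the depth-corrected accesson columns), all peaks of
#' the passing accessons are collected, and every gene whose TSS window
#' intersects at least one of those peaks is reported.
#'
#' @param M an [build_accesson_matrix()] result.
#' @param assignment the [group_peaks()] result that built `M`.
#' @param labels per-cell cluster labels.
#' @param map gene-to-peak map from [map_peaks_to_genes()].
#' @param target_cluster the cluster to contrast against the rest.
#' @inheritParams differential_features
#' @return character vector of gene names (possibly empty).
#' @export
differential_genes_via_accessons <- function(M, assignment, labels, map,
                                             target_cluster,
                                             p_cutoff = 0.05,
                                             fc_cutoff = 2.0, eps = 0.01) {
  stopifnot(inherits(M, "accesson_matrix"),
            inherits(assignment, "accesson_assignment"))
  tab <- differential_features(M, labels, target_cluster,
                               p_cutoff = p_cutoff, fc_cutoff = fc_cutoff,
                               eps = eps)
  hits <- which(tab$pass)
  if (length(hits) == 0) return(character(0))
  peak_hit <- assignment$labels %in% hits
  genes <- names(map)[vapply(map, function(idx) any(peak_hit[idx]), logical(1))]
  genes
}
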