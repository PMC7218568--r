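#' Associate two cluster systems by differential-gene overlap
#'
#' For every pair of clusters (a, b) from two experiments (e.g. one
#' chromatin-derived, one transcriptome-derived), builds the 2x2 table
#' G11 = |A_a intersect B_b|, G12 = |A_a \ B_b|, G21 = |B_b \ A_a|,
#' G22 = |universe| - G11 - G12 - G21, applies a one-sided (enrichment)
#' Fisher's exact test, and fills a matrix with -log(p) (natural log).
#' Row z-scores and then column z-scores of that matrix (sequential,
#' population SD) highlight which cluster pairs correspond.
#'
#' @param sets_a named list of differential gene sets, one per cluster of
#'   experiment A.
#' @param sets_b same for experiment B.
#' @param universe character vector of all testable genes (>= 10); every
#'   set must be contained in it.
#' @return An object of class `association_matrix`: list with `neglogp`
#'   (clusters A x clusters B), `z_rows`, `z_cols` (column z-score of
#'   `z_rows`), and `p_value`.
#' @export
fisher_association <- function(sets_a, sets_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) < 10)
    stop("universe must contain at least 10 genes")
  sets_a <- lapply(sets_a, function(s) unique(as.character(s)))
  sets_b <- lapply(sets_b, function(s) unique(as.character(s)))
  for (s in c(sets_a, sets_b))
    if (length(setdiff(s, universe)) > 0)
      stop("differential sets must be subsets of the universe")
  n_u <- length(universe)
  p <- matrix(NA_real_, length(sets_a), length(sets_b),
              dimnames = list(names(sets_a), names(sets_b)))
  for (a in seq_along(sets_a)) {
    for (b in seq_along(sets_b)) {
      g11 <- length(intersect(sets_a[[a]], sets_b[[b]]))
      g12 <- length(sets_a[[a]]) - g11
      g21 <- length(sets_b[[b]]) - g11
      g22 <- n_u - g11 - g12 - g21
      if (g22 < 0) stop("sets larger than the universe")
      p[a, b] <- fisher.test(matrix(c(g11, g12, g21, g22), 2, byrow = TRUE),
                             alternative = "greater")$p.value
    }
  }
  neglogp <- -log(p)
  z_rows <- .zscore_rows(neglogp)
  z_cols <- .zscore_cols(z_rows)
  structure(list(neglogp = neglogp, z_rows = z_rows, z_cols = z_cols,
                 p_value = p),
            class = "association_matrix")
}

#' @exportS3Method base::print
print.association_matrix <- function(x, ...) {
  cat("association_matrix:", nrow(x$neglogp), "x", ncol(x$neglogp),
      "cluster pairs; max -log(p) =", sprintf("%.2f", max(x$neglogp)), "\n")
  invisible(x)
}

#' Per-cell annotation scores from accesson-level weights
#'
#' Given a (terms x accessons) weight matrix — e.g. -log(p) of GO terms
#' or -log(E) of motifs on each accesson's peaks, produced by external
#' enrichment services — scores every cell by the weighted sum of its
#' accesson counts, \eqn{score_{ij} = \sum_k W_{ik} M_{jk}}, and z-scores
#' each term row across cells (population SD; constant rows map to
#' zeros).
#'
#' @param weights terms-by-accessons numeric matrix with non-negative
#'   entries; column count must equal the number of accessons.
#' @param M an [build_accesson_matrix()] result or cells-by-accessons
#'   count matrix.
#' @return list with `raw` and `zscore`, both terms x cells.
#' @export
weighted_annotation_scores <- function(weights, M) {
  m_raw <- if (inherits(M, "accesson_matrix")) M$raw else as.matrix(M)
  weights <- as.matrix(weights)
  if (ncol(weights) != ncol(m_raw))
    stop("weights have ", ncol(weights), " accesson columns but the ",
         "accesson matrix has ", ncol(m_raw))
  raw <- weights %*% t(m_raw) # terms x cells
  list(raw = raw, zscore = .zscore_rows(raw))
}

#' Call candidate super-enhancers from accesson structure
#'
#' A super-enhancer candidate is a genomic window densely populated by
#' peaks of one accesson. Windows of width `window` slide by `step`
#' along each chromosome; in every window holding at least `min_peaks`
#' peaks in total, the fraction of the window's peaks contributed by each
#' accesson present is computed, and those (window, accesson) fractions
#' genome-wide form the empirical null. A candidate — a (window,
#' accesson) pair with at least `min_peaks` member peaks — is called when
#' the upper-tail rank of its fraction within that population (candidate
#' included, so p is never 0) falls below `p_cutoff`. Overlapping called
#' windows of the same accesson are merged into one interval spanning
#' their union; the reported statistics are those of the best window.
#' Peaks are assigned to windows by their midpoint.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`) or
#'   [fragment_matrix()].
#' @param assignment an [group_peaks()] result covering the peaks.
#' @param window window width in bp (default 1e6).
#' @param step slide step in bp (default 1e5).
#' @param p_cutoff empirical p-value cutoff (default 0.01).
#' @param min_peaks minimum same-accesson peaks for a candidate and
#'   minimum total peaks for a window to enter the null (default 10).
#' @return data.frame with one row per merged call: `chrom`, `start`,
#'   `end`, `accesson`, `n_peaks`, `fraction`, `p_value`. Zero rows when
#'   nothing qualifies.
#' @export
call_super_enhancers <- function(peaks, assignment, window = 1e6,
                                 step = 1e5, p_cutoff = 0.01,
                                 min_peaks = 10) {
  if (inherits(peaks, "fragment_matrix")) peaks <- peaks$peaks
  peaks <- validate_peaks(peaks)
  stopifnot(inherits(assignment, "accesson_assignment"))
  if (nrow(peaks) != length(assignment$labels))
    stop("assignment does not cover the peaks")
  mid <- (peaks$start + peaks$end) / 2
  # every window [w*step, w*step + window) containing the midpoint
  w_hi <- floor(mid / step)
  w_lo <- pmax(floor((mid - window) / step) + 1, 0)
  n_win <- w_hi - w_lo + 1
  inc <- data.frame(
    chrom = rep(peaks$chrom, n_win),
    win = unlist(mapply(seq, w_lo, w_hi, SIMPLIFY = FALSE)),
    accesson = rep(assignment$labels, n_win))
  key_win <- paste(inc$chrom, inc$win)
  totals <- table(key_win)
  cnt <- stats::aggregate(list(n = rep(1L, nrow(inc))),
                          inc[c("chrom", "win", "accesson")], sum)
  cnt$total <- as.integer(totals[paste(cnt$chrom, cnt$win)])
  pop <- cnt[cnt$total >= min_peaks, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), accesson = integer(0),
                      n_peaks = integer(0), fraction = numeric(0),
                      p_value = numeric(0))
  if (nrow(pop) == 0) {
    message("no window holds >= ", min_peaks, " peaks; no candidates")
    return(empty)
  }
  pop$fraction <- pop$n / pop$total
  frs <- sort(pop$fraction)
  n_pop <- length(frs)
  # upper-tail empirical rank, candidate included in the population
  pop$p_value <- (n_pop - findInterval(pop$fraction - 1e-12, frs)) / n_pop
  calls <- pop[pop$n >= min_peaks & pop$p_value < p_cutoff, , drop = FALSE]
  if (nrow(calls) == 0) return(empty)
  calls$start <- calls$win * step
  calls$end <- calls$start + window
  # merge overlapping windows of the same accesson on the same chromosome
  calls <- calls[order(calls$chrom, calls$accesson, calls$start), ]
  merged <- list()
  cur <- calls[1, ]
  flush <- function(cur) data.frame(
    chrom = cur$chrom, start = cur$start, end = cur$end,
    accesson = cur$accesson, n_peaks = cur$n, fraction = cur$fraction,
    p_value = cur$p_value)
  for (r in seq_len(nrow(calls))[-1]) {
    row <- calls[r, ]
    if (row$chrom == cur$chrom && row$accesson == cur$accesson &&
        row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      if (row$fraction > cur$fraction) {
        cur$fraction <- row$fraction
        cur$n <- row$n
        cur$p_value <- row$p_value
      }
      cur$p_value <- min(cur$p_value, row$p_value)
    } else {
      merged[[length(merged) + 1]] <- flush(cur)
      cur <- row
    }
  }
  merged[[length(merged) + 1]] <- flush(cur)
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), ]
}
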