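#' Fragment count matrix container
#'
#' Bundles a sparse non-negative integer cells-by-peaks count matrix with
#' its cell barcodes and peak intervals. Peak coordinates are 0-based
#' half-open (BED convention) throughout the package.
#'
#' @param counts sparse (or dense) non-negative integer matrix, rows =
#'   cells, columns = peaks.
#' @param barcodes character vector of unique cell identifiers, one per row.
#' @param peaks data.frame with columns `chrom`, `start`, `end` and
#'   optionally `qscore` (the -log10 Q-value from peak calling), one row
#'   per column of `counts`.
#' @return An object of class `fragment_matrix`: a list with elements
#'   `counts` (dgCMatrix), `barcodes`, and `peaks`.
#' @export
fragment_matrix <- function(counts, barcodes, peaks) {
  # * 1 promotes pattern/logical storage (e.g. an all-ones MTX read back
  # as a pattern matrix) to numeric
  counts <- as(as(Matrix::Matrix(counts, sparse = TRUE) * 1,
                  "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0))
    stop("fragment counts must be non-negative")
  if (any(counts@x != round(counts@x)))
    stop("fragment counts must be integral")
  counts <- Matrix::drop0(counts)
  barcodes <- as.character(barcodes)
  if (length(barcodes) != nrow(counts))
    stop("barcode count (", length(barcodes), ") does not match matrix rows (",
         nrow(counts), ")")
  if (anyDuplicated(barcodes))
    stop("duplicate cell barcodes")
  peaks <- validate_peaks(peaks)
  if (nrow(peaks) != ncol(counts))
    stop("peak count (", nrow(peaks), ") does not match matrix columns (",
         ncol(counts), ")")
  rownames(counts) <- barcodes
  structure(list(counts = counts, barcodes = barcodes, peaks = peaks),
            class = "fragment_matrix")
}

validate_peaks <- function(peaks) {
  peaks <- as.data.frame(peaks)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(peaks)))
    stop("peaks need columns chrom, start, end")
  peaks$chrom <- as.character(peaks$chrom)
  peaks$start <- as.numeric(peaks$start)
  peaks$end <- as.numeric(peaks$end)
  if (any(peaks$start >= peaks$end))
    stop("every peak must satisfy start < end")
  if (any(peaks$start < 0))
    stop("peak coordinates must be non-negative")
  if (!"qscore" %in% names(peaks)) peaks$qscore <- NA_real_
  rownames(peaks) <- NULL
  peaks[c("chrom", "start", "end", "qscore")]
}

#' @exportS3Method base::dim
dim.fragment_matrix <- function(x) dim(x$counts)

#' @exportS3Method base::print
print.fragment_matrix <- function(x, ...) {
  cat("fragment_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "peaks\n")
  nnz <- length(x$counts@x)
  cat(sprintf("  %d stored counts (%.2f%% dense), %d chromosome(s)\n",
              nnz, 100 * nnz / prod(dim(x$counts)),
              length(unique(x$peaks$chrom))))
  if (!all(is.na(x$peaks$qscore)))
    cat(sprintf("  peak qscore range: [%.3g, %.3g]\n",
                min(x$peaks$qscore), max(x$peaks$qscore)))
  invisible(x)
}

#' Read a sparse fragment count matrix with its sidecar files
#'
#' Reads a MatrixMarket coordinate file plus a BED-like peak file
#' (`chrom start end [qscore]`, headerless, 0-based half-open) and a
#' one-barcode-per-line text file. The stored matrix may be either
#' cells-by-peaks or peaks-by-cells; the orientation is resolved by
#' matching the MTX dimensions against the sidecar file lengths. A square
#' matrix is ambiguous and requires an explicit `orientation`.
#'
#' @param mtx_path path to the `.mtx` file.
#' @param peaks_path path to the peak interval file.
#' @param barcodes_path path to the barcode list.
#' @param orientation `"auto"` (default), `"cells"` (rows are cells), or
#'   `"peaks"` (rows are peaks).
#' @return A [fragment_matrix()] in cells-by-peaks orientation.
#' @export
read_fragment_matrix <- function(mtx_path, peaks_path, barcodes_path,
                                 orientation = c("auto", "cells", "peaks")) {
  orientation <- match.arg(orientation)
  for (p in c(mtx_path, peaks_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop("malformed MTX file '", mtx_path,
                                         "': ", conditionMessage(e)))
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  peaks <- read_peaks(peaks_path)
  nb <- length(barcodes)
  np <- nrow(peaks)

  fits_cells <- nrow(m) == nb && ncol(m) == np
  fits_peaks <- nrow(m) == np && ncol(m) == nb
  m <- switch(orientation,
    cells = if (fits_cells) m else stop(
      "MTX dimensions ", nrow(m), "x", ncol(m),
      " do not match cells-by-peaks sidecars (", nb, " barcodes, ",
      np, " peaks)"),
    peaks = if (fits_peaks) Matrix::t(m) else stop(
      "MTX dimensions ", nrow(m), "x", ncol(m),
      " do not match peaks-by-cells sidecars (", np, " peaks, ",
      nb, " barcodes)"),
    auto = {
      if (fits_cells && fits_peaks && nb != np) m
      else if (fits_cells && fits_peaks)
        stop("square matrix: orientation is ambiguous, pass orientation=")
      else if (fits_cells) m
      else if (fits_peaks) Matrix::t(m)
      else stop("MTX dimensions ", nrow(m), "x", ncol(m),
                " match neither orientation of the sidecar files (",
                nb, " barcodes, ", np, " peaks)")
    })
  fragment_matrix(m, barcodes, peaks)
}

#' Read a BED-like peak interval file
#'
#' @param path headerless TSV with columns `chrom start end [qscore]`.
#' @return data.frame with columns chrom, start, end, qscore.
#' @export
read_peaks <- function(path) {
  peaks <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
  if (ncol(peaks) < 3) stop("peak file needs at least 3 columns")
  names(peaks)[1:3] <- c("chrom", "start", "end")
  if (ncol(peaks) >= 4) names(peaks)[4] <- "qscore"
  validate_peaks(peaks[, seq_len(min(4, ncol(peaks)))])
}

#' Write a fragment matrix as MTX + BED + barcode sidecars
#'
#' Inverse of [read_fragment_matrix()]; the matrix is stored cells-by-peaks.
#'
#' @param x a [fragment_matrix()].
#' @param mtx_path,peaks_path,barcodes_path output paths.
#' @return invisibly, the three paths.
#' @export
write_fragment_matrix <- function(x, mtx_path, peaks_path, barcodes_path) {
  stopifnot(inherits(x, "fragment_matrix"))
  Matrix::writeMM(x$counts, mtx_path)
  pk <- x$peaks
  if (all(is.na(pk$qscore))) pk$qscore <- NULL
  write.table(pk, peaks_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(x$barcodes, barcodes_path)
  invisible(c(mtx_path, peaks_path, barcodes_path))
}

#' Per-cell quality-control metrics
#'
#' Computes the total number of valid fragments per cell (`n_fragments`),
#' the fraction of fragments falling in peaks (`frac_in_peaks`), and, when
#' a TSS table is supplied, the fraction of in-peak counts lying in peaks
#' that intersect any TSS +/- `tss_window` bp window (`frac_tss`). When no
#' external totals are available the in-peak row sum is used as the total,
#' so `frac_in_peaks` degenerates to 1 and filtering on it is a no-op.
#'
#' @param x a [fragment_matrix()].
#' @param totals optional per-cell total fragment counts, in row order or
#'   named by barcode.
#' @param tss optional TSS table (`gene`, `chrom`, `tss`, `strand`), see
#'   [read_tss()].
#' @param tss_window half-width in bp of the TSS window (default 2000).
#' @return data.frame with columns `barcode`, `n_fragments`,
#'   `frac_in_peaks`, and (if `tss` given) `frac_tss`.
#' @export
compute_cell_qc <- function(x, totals = NULL, tss = NULL, tss_window = 2000) {
  stopifnot(inherits(x, "fragment_matrix"))
  in_peak <- Matrix::rowSums(x$counts)
  if (is.null(totals)) {
    n_frag <- in_peak
    frac <- rep(1, length(in_peak))
    frac[n_frag == 0] <- 0
  } else {
    if (!is.null(names(totals))) {
      if (!all(x$barcodes %in% names(totals)))
        stop("totals must cover every barcode")
      totals <- totals[x$barcodes]
    }
    if (length(totals) != length(x$barcodes))
      stop("need one total per barcode")
    if (any(totals < in_peak))
      stop("per-cell totals smaller than in-peak counts for ",
           sum(totals < in_peak), " cell(s)")
    n_frag <- as.numeric(totals)
    frac <- ifelse(n_frag > 0, in_peak / n_frag, 0)
  }
  qc <- data.frame(barcode = x$barcodes, n_fragments = n_frag,
                   frac_in_peaks = frac, stringsAsFactors = FALSE)
  if (!is.null(tss)) {
    tss <- validate_tss(tss)
    hit <- peaks_near_tss(x$peaks, tss, tss_window)
    tss_counts <- Matrix::rowSums(x$counts[, hit, drop = FALSE])
    qc$frac_tss <- ifelse(in_peak > 0, tss_counts / in_peak, 0)
  }
  qc
}

# logical index of peaks whose half-open interval intersects any
# [tss - window, tss + window) half-open window on the same chromosome
peaks_near_tss <- function(peaks, tss, window) {
  pk <- GenomicRanges::GRanges(peaks$chrom,
          IRanges::IRanges(start = peaks$start + 1, end = peaks$end))
  win <- GenomicRanges::GRanges(tss$chrom,
          IRanges::IRanges(start = pmax(tss$tss - window, 0) + 1,
                           end = tss$tss + window))
  # suppress the informational seqlevels notice when chromosome sets differ
  hits <- suppressWarnings(GenomicRanges::findOverlaps(pk, win))
  out <- rep(FALSE, nrow(peaks))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Filter cells on QC metrics
#'
#' Retains exactly the cells with `frac_in_peaks > pf_cutoff` and
#' `n_fragments > nf_cutoff` (strict inequalities). Row order of the
#' retained cells is preserved and the peak set is unchanged.
#'
#' @param x a [fragment_matrix()].
#' @param qc QC table from [compute_cell_qc()] covering all barcodes.
#' @param pf_cutoff minimum fraction of fragments in peaks (exclusive).
#' @param nf_cutoff minimum total fragments (exclusive).
#' @return filtered [fragment_matrix()].
#' @export
filter_cells <- function(x, qc, pf_cutoff = 0.2, nf_cutoff = 2000) {
  stopifnot(inherits(x, "fragment_matrix"))
  if (!all(x$barcodes %in% qc$barcode))
    stop("QC table does not cover every barcode")
  qc <- qc[match(x$barcodes, qc$barcode), ]
  keep <- qc$frac_in_peaks > pf_cutoff & qc$n_fragments > nf_cutoff
  if (!any(keep))
    stop("no cells pass QC (0 of ", length(keep), " with frac_in_peaks > ",
         pf_cutoff, " and n_fragments > ", nf_cutoff, ")")
  fragment_matrix(x$counts[keep, , drop = FALSE], x$barcodes[keep], x$peaks)
}

#' Filter peaks on quality score
#'
#' Retains peaks with `qscore >= min_qscore`; when `max_peaks` is given,
#' additionally keeps only the top `max_peaks` peaks by qscore, breaking
#' ties by original file order. Cells are unchanged.
#'
#' @param x a [fragment_matrix()].
#' @param min_qscore minimum -log10 Q-value (inclusive); 0 disables.
#' @param max_peaks optional cap on the number of retained peaks.
#' @return filtered [fragment_matrix()].
#' @export
filter_peaks <- function(x, min_qscore = 0, max_peaks = NULL) {
  stopifnot(inherits(x, "fragment_matrix"))
  q <- x$peaks$qscore
  if ((min_qscore > 0 || !is.null(max_peaks)) && all(is.na(q)))
    stop("peak qscore column absent but a quality filter was requested")
  keep <- if (min_qscore > 0) which(!is.na(q) & q >= min_qscore)
          else seq_len(nrow(x$peaks))
  if (!is.null(max_peaks) && length(keep) > max_peaks) {
    ord <- keep[order(-q[keep], keep)]
    keep <- sort(ord[seq_len(max_peaks)])
  }
  if (length(keep) == 0) stop("no peaks pass the quality filter")
  fragment_matrix(x$counts[, keep, drop = FALSE], x$barcodes,
                  x$peaks[keep, , drop = FALSE])
}
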