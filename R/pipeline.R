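#' Default pipeline configuration
#'
#' All tunable parameters of the file-based pipeline with their default
#' values: 600 accessons, K = 10 peak neighbors, 40 principal components,
#' z-score accesson normalization, 20 cell neighbors, Louvain resolution
#' 1.0, a 20 kb TSS window for gene scores, a 1 Mb super-enhancer window,
#' and p / fold-change cutoffs of 0.05 / 2.0 for differential analysis.
#'
#' @param ... overrides of any default field.
#' @return named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(mtx = NULL, peaks = NULL, barcodes = NULL, tss = NULL,
              totals = NULL, orientation = "auto",
              pf_cutoff = 0, nf_cutoff = 0, min_qscore = 0,
              max_peaks = NULL, n_accessons = 600, peak_knn = 10,
              n_pcs = 40, norm = "zscore", cell_knn = 20,
              resolution = 1.0, n_clusters = NULL, gene_window = 20000,
              se_window = 1e6, se_step = 1e5, se_p = 0.01,
              p_cutoff = 0.05, fc_cutoff = 2.0, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Run the file-based analysis pipeline
#'
#' Chains the stages end to end — read the sparse matrix and sidecars
#' (`io`), QC and peak filtering (`filter`), the accesson model and cell
#' clustering (`fit`), optional gene scoring (`genescore`) — and writes
#' every intermediate artifact plus a machine-readable JSON manifest to
#' `out_dir`. A failing stage aborts with the stage named. Re-running
#' with an identical configuration reproduces identical outputs.
#'
#' @param config list from [pipeline_config()], or a path to a YAML file
#'   holding the same fields.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the [accesson_fit()] object.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  fm <- stage("io", {
    if (is.null(config$mtx)) stop("config$mtx is required")
    read_fragment_matrix(config$mtx, config$peaks, config$barcodes,
                         orientation = config$orientation)
  })

  fm <- stage("filter", {
    out <- fm
    if (config$min_qscore > 0 || !is.null(config$max_peaks))
      out <- filter_peaks(out, config$min_qscore, config$max_peaks)
    if (config$pf_cutoff > 0 || config$nf_cutoff > 0) {
      totals <- NULL
      if (!is.null(config$totals)) {
        tt <- read.table(config$totals, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
        totals <- setNames(tt[[2]], tt[[1]])
      } else if (config$pf_cutoff > 0) {
        warning("no per-cell totals supplied; frac_in_peaks is 1 for all ",
                "cells and the pf_cutoff filter is a no-op")
      }
      qc <- compute_cell_qc(out, totals = totals)
      out <- filter_cells(out, qc, config$pf_cutoff, config$nf_cutoff)
    }
    out
  })

  fit <- stage("fit", accesson_fit(
    fm, n_accessons = config$n_accessons, peak_knn = config$peak_knn,
    n_pcs = config$n_pcs, norm = config$norm, cell_knn = config$cell_knn,
    resolution = config$resolution, n_clusters = config$n_clusters,
    seed = config$seed))

  stage("write", {
    write.table(data.frame(peak_index = seq_along(fit$assignment$labels),
                           accesson_id = fit$assignment$labels),
                file.path(out_dir, "accesson_assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    Matrix::writeMM(Matrix::Matrix(fit$M$raw, sparse = TRUE),
                    file.path(out_dir, "accesson_matrix.mtx"))
    write.table(round(fit$M$normalized, 6),
                file.path(out_dir, "accesson_matrix_normalized.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(data.frame(barcode = fm$barcodes, cluster = fit$cluster),
                file.path(out_dir, "cluster_labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emb <- accesson_pca(fit$M, n_pcs = min(5, fit$assignment$n_accessons))
    coords <- emb$coords
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
    write.table(data.frame(barcode = fm$barcodes, coords),
                file.path(out_dir, "cell_embedding.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (!is.null(config$tss)) {
    stage("genescore", {
      tss <- read_tss(config$tss)
      map <- map_peaks_to_genes(fm$peaks, tss, window = config$gene_window)
      gs <- gene_scores(fm, map)
      write.table(round(gs$normalized, 4),
                  file.path(out_dir, "gene_scores.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("accessons")),
    r_version = as.character(getRversion()),
    parameters = config[!vapply(config, is.null, logical(1))],
    n_cells = nrow(fm$counts), n_peaks = ncol(fm$counts),
    n_accessons = fit$assignment$n_accessons,
    n_clusters = fit$n_clusters,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(fit)
}
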