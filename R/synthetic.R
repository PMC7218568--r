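#' Configuration for the synthetic scATAC-seq generator
#'
#' Describes a planted-structure dataset: `n_blocks` co-accessible peak
#' blocks (the ground-truth accessons) spread over `n_peaks` peaks,
#' `n_cell_types` cell types with `cells_per_type` cells each, Poisson
#' count emission with lognormal per-cell depth multipliers, and one
#' planted super-enhancer locus whose peaks all belong to a single block
#' and sit inside a compact genomic span.
#'
#' Each block is "on" in exactly one cell type (blocks cycle over types).
#' Within its on-type, a block fluctuates from cell to cell: a Bernoulli
#' gate (probability `gate_prob`) switches the whole block between a high
#' sub-rate `open_rate_high * (1 + gate_amplitude)` and a low sub-rate
#' `open_rate_high * (1 - gate_amplitude)`, so the expected rate of an
#' open block is exactly `open_rate_high` while all peaks of the block
#' share the cell's activity state. This co-fluctuation — the statistical
#' signature accessons are designed to detect — is what gives every block
#' its own identifiable accessibility pattern even among blocks that
#' share a cell type; blocks differing only through a constant per-type
#' rate would be statistically indistinguishable from each other. Closed
#' peaks emit counts at `open_rate_low`. All rates are scaled by the
#' cell's depth multiplier.
#'
#' In gradient mode (`gradient = TRUE`) the discrete types are replaced
#' by a latent pseudotime t ~ U(0, 1): odd blocks open up linearly with
#' t, even blocks close down, so the first principal component of the
#' accesson matrix should recover t.
#'
#' @param n_cell_types number of planted cell types (default 3).
#' @param cells_per_type cells per type (default 50, >= 2).
#' @param n_peaks total peaks (default 1200).
#' @param n_blocks planted peak blocks (default 30, <= n_peaks).
#' @param open_rate_high,open_rate_low expected counts per peak and cell
#'   (before depth scaling) for open / closed peaks (defaults 0.5, 0.02).
#' @param gate_prob per-cell probability that an on-type block is in its
#'   high-activity state (default 0.5).
#' @param gate_amplitude relative swing of the two activity states around
#'   `open_rate_high` (default 0.9, i.e. sub-rates 1.9x and 0.1x the open
#'   rate).
#' @param depth_mu,depth_sigma lognormal meanlog / sdlog of the per-cell
#'   depth multiplier (defaults 0, 0.25).
#' @param n_chrom,chrom_length synthetic genome shape (defaults 5
#'   chromosomes of 20 Mb).
#' @param peak_width width of every peak in bp (default 500).
#' @param se_block block providing the super-enhancer peaks (default:
#'   the last block).
#' @param se_chrom,se_start,se_span,se_n_peaks placement of the planted
#'   super-enhancer locus (default: 20 peaks within 0.5 Mb at
#'   chr1:2,000,000).
#' @param gradient emit a latent-pseudotime gradient instead of discrete
#'   types (default FALSE).
#' @param seed integer seed making the dataset fully reproducible.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cell_types = 3, cells_per_type = 50,
                             n_peaks = 1200, n_blocks = 30,
                             open_rate_high = 0.5, open_rate_low = 0.02,
                             gate_prob = 0.5, gate_amplitude = 0.9,
                             depth_mu = 0,
                             depth_sigma = 0.25, n_chrom = 5,
                             chrom_length = 2e7, peak_width = 500,
                             se_block = n_blocks, se_chrom = "chr1",
                             se_start = 2e6, se_span = 5e5,
                             se_n_peaks = 20, gradient = FALSE, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_blocks > cfg$n_peaks) stop("more blocks than peaks")
  if (cfg$cells_per_type < 2) stop("cells_per_type must be >= 2")
  if (cfg$open_rate_low < 0 || cfg$open_rate_high < cfg$open_rate_low)
    stop("need 0 <= open_rate_low <= open_rate_high")
  if (cfg$gate_amplitude < 0 || cfg$gate_amplitude > 1)
    stop("gate_amplitude must lie in [0, 1]")
  if (cfg$se_block > cfg$n_blocks) stop("se_block out of range")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic scATAC-seq dataset with planted structure
#'
#' Draws a sparse cells-by-peaks count matrix under the model described
#' in [synthetic_config()] and returns it together with the ground truth
#' (cell types or latent pseudotime, the peak-to-block map, and the
#' planted super-enhancer interval). Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return list with `data` (a [fragment_matrix()]) and `truth` (list
#'   with `cell_type`, `pseudotime`, `block`, `se`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_types <- config$n_cell_types
  n_cells <- n_types * config$cells_per_type
  n_peaks <- config$n_peaks
  n_blocks <- config$n_blocks

  block <- rep(seq_len(n_blocks), length.out = n_peaks)
  block <- sort(block) # contiguous blocks of near-equal size
  block_type <- ((seq_len(n_blocks) - 1) %% n_types) + 1

  depth <- rlnorm(n_cells, config$depth_mu, config$depth_sigma)

  if (config$gradient) {
    pt <- runif(n_cells)
    cell_type <- rep(NA_character_, n_cells)
    up <- (seq_len(n_blocks) %% 2) == 1
    # cells x blocks expected rate
    f <- outer(pt, up, function(t, u) ifelse(u, t, 1 - t))
    rate_block <- config$open_rate_low +
      (config$open_rate_high - config$open_rate_low) * f
  } else {
    pt <- NULL
    cell_type <- paste0("type", rep(seq_len(n_types),
                                    each = config$cells_per_type))
    type_id <- rep(seq_len(n_types), each = config$cells_per_type)
    on <- outer(type_id, block_type, `==`)
    gate <- matrix(rbinom(n_cells * n_blocks, 1, config$gate_prob),
                   n_cells, n_blocks)
    activity <- 1 + config$gate_amplitude * (2 * gate - 1)
    rate_block <- ifelse(on, config$open_rate_high * activity,
                         config$open_rate_low)
  }

  lambda <- rate_block[, block, drop = FALSE] * depth
  counts <- matrix(rpois(length(lambda), lambda), n_cells, n_peaks)

  peaks <- random_peak_intervals(config, block)
  barcodes <- sprintf("cell%04d", seq_len(n_cells))
  fm <- fragment_matrix(counts, barcodes, peaks$peaks)
  list(data = fm,
       truth = list(cell_type = cell_type, pseudotime = pt, block = block,
                    se = peaks$se))
}

# place peaks on the synthetic genome; the super-enhancer peaks (drawn
# from one block) land inside the configured span, everything else is
# uniform. Returns the peak table plus the planted interval description.
random_peak_intervals <- function(config, block) {
  n_peaks <- length(block)
  w <- config$peak_width
  chrom <- paste0("chr", sample.int(config$n_chrom, n_peaks, replace = TRUE))
  start <- floor(runif(n_peaks, 0, config$chrom_length - w))
  se_members <- which(block == config$se_block)
  se <- NULL
  if (config$se_n_peaks > 0) {
    if (length(se_members) < config$se_n_peaks)
      stop("super-enhancer block has fewer peaks than se_n_peaks")
    se_idx <- se_members[seq_len(config$se_n_peaks)]
    chrom[se_idx] <- config$se_chrom
    start[se_idx] <- floor(runif(length(se_idx), config$se_start,
                                 config$se_start + config$se_span - w))
    se <- data.frame(chrom = config$se_chrom, start = config$se_start,
                     end = config$se_start + config$se_span,
                     block = config$se_block)
  }
  peaks <- data.frame(chrom = chrom, start = start, end = start + w,
                      qscore = round(5 + stats::rexp(n_peaks, 1 / 20), 2))
  list(peaks = peaks, se = se)
}

#' Down-sample sequencing reads
#'
#' Emulates lower sequencing depth: every stored count is replaced by a
#' Binomial(count, fraction) draw, i.e. each read is kept independently
#' with probability `fraction`.
#'
#' @param x a [fragment_matrix()].
#' @param fraction read-retention probability in \[0, 1\].
#' @param seed integer seed.
#' @return a [fragment_matrix()] with the thinned counts.
#' @export
downsample_reads <- function(x, fraction, seed = 1) {
  stopifnot(inherits(x, "fragment_matrix"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  set.seed(seed)
  counts <- x$counts
  counts@x <- as.numeric(rbinom(length(counts@x), counts@x, fraction))
  fragment_matrix(Matrix::drop0(counts), x$barcodes, x$peaks)
}

#' Zero out random matrix elements
#'
#' Emulates dropout noise: exactly `round(fraction * nnz)` uniformly
#' chosen nonzero entries of the count matrix are set to zero.
#'
#' @param x a [fragment_matrix()].
#' @param fraction fraction of nonzero entries to zero, in \[0, 1\].
#' @param seed integer seed.
#' @return a [fragment_matrix()] with the corrupted counts.
#' @export
inject_noise <- function(x, fraction, seed = 1) {
  stopifnot(inherits(x, "fragment_matrix"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  set.seed(seed)
  counts <- x$counts
  nnz <- length(counts@x)
  k <- round(fraction * nnz)
  if (k > 0) counts@x[sample.int(nnz, k)] <- 0
  fragment_matrix(Matrix::drop0(counts), x$barcodes, x$peaks)
}
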