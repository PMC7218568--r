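# shared fixture builders; everything is generated in code at test time

# fragment_matrix from a plain matrix, with auto-generated peak intervals
tiny_fm <- function(counts, chrom = NULL, start = NULL, width = 500,
                    qscore = NULL) {
  counts <- as.matrix(counts)
  np <- ncol(counts)
  if (is.null(chrom)) chrom <- rep("chr1", np)
  if (is.null(start)) start <- seq(0, by = 10000, length.out = np)
  peaks <- data.frame(chrom = chrom, start = start, end = start + width)
  if (!is.null(qscore)) peaks$qscore <- qscore
  fragment_matrix(counts, sprintf("bc%03d", seq_len(nrow(counts))), peaks)
}

# scaled-down planted dataset for unit tests (3 types x 20 cells, 10 blocks)
small_config <- function(...) {
  args <- list(cells_per_type = 20, n_peaks = 300, n_blocks = 10,
               se_n_peaks = 15)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# independent ARI oracle: pair-counting closed form, never the
# contingency formula used by the implementation
ari_pairs <- function(t_lab, p_lab) {
  st <- outer(t_lab, t_lab, `==`)[upper.tri(diag(length(t_lab)))]
  sp <- outer(p_lab, p_lab, `==`)[upper.tri(diag(length(p_lab)))]
  a <- sum(st & sp); b <- sum(st & !sp)
  c <- sum(!st & sp); d <- sum(!st & !sp)
  denom <- (a + b) * (b + d) + (a + c) * (c + d)
  if (denom == 0) return(1)
  2 * (a * d - b * c) / denom
}

# accesson assignment built by hand (bypasses group_peaks) for tests that
# plant their own peak partition
manual_assignment <- function(labels, n = max(labels)) {
  structure(list(labels = as.integer(labels), n_accessons = as.integer(n)),
            class = "accesson_assignment")
}

# random sparse count matrix for conservation-style properties
random_counts <- function(n_cells, n_peaks, density = 0.2, max_count = 8) {
  m <- matrix(0, n_cells, n_peaks)
  nz <- round(density * n_cells * n_peaks)
  idx <- sample(n_cells * n_peaks, nz)
  m[idx] <- sample(max_count, nz, replace = TRUE)
  m
}
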