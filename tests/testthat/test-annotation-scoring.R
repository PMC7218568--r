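test_that("Fisher association matches the hypergeometric tail oracle", {
  universe <- paste0("g", 1:100)
  # |A| = 20, |B| = 20, overlap 15
  a_set <- universe[1:20]
  b_set <- universe[6:25]
  res <- fisher_association(list(a = a_set), list(b = b_set), universe)
  oracle <- sum(dhyper(15:20, 20, 80, 20))
  expect_equal(res$p_value[1, 1], oracle, tolerance = 1e-12)
  expect_equal(res$neglogp[1, 1], -log(oracle))
  # swapping the two sets leaves p unchanged
  swapped <- fisher_association(list(b = b_set), list(a = a_set), universe)
  expect_equal(swapped$p_value[1, 1], res$p_value[1, 1])
  # empty differential set: p = 1, -log(p) = 0
  res0 <- fisher_association(list(a = character(0)), list(b = b_set),
                             universe)
  expect_equal(res0$p_value[1, 1], 1)
  expect_equal(res0$neglogp[1, 1], 0)

  expect_error(fisher_association(list(a = "not-there"), list(b = b_set),
                                  universe), "subsets")
  expect_error(fisher_association(list(a = "g1"), list(b = "g2"),
                                  paste0("g", 1:5)), "at least 10")
})

test_that("Fisher p equals the tail sum on random tables, monotonically", {
  set.seed(123)
  universe <- paste0("g", 1:50)
  ps <- numeric(0)
  for (i in 1:200) {
    na <- sample(0:50, 1); nb <- sample(0:50, 1)
    a_set <- sample(universe, na)
    b_set <- sample(universe, nb)
    res <- fisher_association(list(a = a_set), list(b = b_set), universe)
    k <- length(intersect(a_set, b_set))
    oracle <- if (na == 0 || nb == 0) 1 else
      sum(dhyper(k:min(na, nb), na, 50 - na, nb))
    expect_equal(res$p_value[1, 1], oracle, tolerance = 1e-10)
    ps <- c(ps, res$p_value[1, 1])
  }
  # -log transform is monotone: smaller p, larger score
  sorted <- sort(ps)
  expect_true(all(diff(-log(sorted)) <= 0))
})

test_that("association z-scores are row-then-column standardized", {
  universe <- paste0("g", 1:60)
  sets_a <- list(a1 = universe[1:15], a2 = universe[16:40],
                 a3 = universe[41:50])
  sets_b <- list(b1 = universe[1:14], b2 = universe[30:45])
  res <- fisher_association(sets_a, sets_b, universe)
  expect_equal(unname(rowMeans(res$z_rows)), rep(0, 3))
  expect_equal(unname(apply(res$z_rows, 1, function(r)
    sqrt(mean((r - mean(r))^2)))), rep(1, 3))
  expect_equal(unname(colMeans(res$z_cols)), rep(0, 2))
  # a cluster pair with constant association z-scores to a zero row
  const <- fisher_association(list(a = universe[1:5]),
                              list(b1 = universe[6:10],
                                   b2 = universe[11:15]), universe)
  expect_equal(unname(const$z_rows[1, ]), rep(0, 2))
})

test_that("weighted annotation scores are the weight-by-count product", {
  M <- structure(list(raw = rbind(c(1, 2), c(3, 4)),
                      normalized = NULL, method = "zscore"),
                 class = "accesson_matrix")
  # identity weights reproduce accesson counts across cells
  idw <- weighted_annotation_scores(diag(2), M)
  expect_equal(unname(idw$raw), t(M$raw))
  # hand-computed product
  L <- rbind(c(1, 0), c(0, 2))
  res <- weighted_annotation_scores(L, M)
  expect_equal(unname(res$raw), rbind(c(1, 3), c(4, 8)))
  # z-scored output is invariant to positive row scaling of the weights
  res2 <- weighted_annotation_scores(L * 7, M)
  expect_equal(res2$zscore, res$zscore)
  expect_equal(unname(res2$raw), 7 * unname(res$raw)) # bilinearity
  # constant raw rows z-score to zero
  resc <- weighted_annotation_scores(rbind(c(0, 0)), M)
  expect_equal(unname(resc$zscore), matrix(0, 1, 2))
  expect_error(weighted_annotation_scores(matrix(1, 2, 3), M),
               "accesson columns")
})

se_background <- function(n_bg = 2000, n_acc = 600, seed = 1) {
  set.seed(seed)
  bg <- data.frame(chrom = paste0("chr", sample(5, n_bg, replace = TRUE)),
                   start = floor(runif(n_bg, 0, 2e7 - 500)))
  bg$end <- bg$start + 500
  list(peaks = bg, labels = sample(n_acc, n_bg, replace = TRUE))
}

test_that("a planted same-accesson locus is called as one super-enhancer", {
  bgd <- se_background(seed = 1)
  set.seed(2)
  se <- data.frame(chrom = "chr1",
                   start = floor(runif(20, 2e6, 2.5e6 - 500)))
  se$end <- se$start + 500
  peaks <- rbind(bgd$peaks, se)
  asg <- manual_assignment(c(bgd$labels, rep(7L, 20)), 600)
  calls <- call_super_enhancers(peaks, asg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$accesson, 7)
  expect_lt(calls$p_value, 0.01)
  # the merged interval contains the planted locus
  expect_true(calls$chrom == "chr1" && calls$start <= 2e6 &&
                calls$end >= 2.5e6)
  expect_gte(calls$n_peaks, 10)

  # invariance under peak-order permutation and chromosome relabeling
  set.seed(3)
  perm <- sample(nrow(peaks))
  relab <- peaks[perm, ]
  relab$chrom <- sub("chr", "k", relab$chrom)
  calls2 <- call_super_enhancers(relab,
                                 manual_assignment(asg$labels[perm], 600))
  expect_equal(calls2$accesson, calls$accesson)
  expect_equal(calls2$start, calls$start)
  expect_equal(calls2$p_value, calls$p_value)
})

test_that("shuffled accesson labels essentially never produce calls", {
  bgd <- se_background(seed = 10)
  n_called <- 0
  for (s in 1:20) {
    set.seed(s)
    lab <- sample(bgd$labels)
    calls <- call_super_enhancers(bgd$peaks, manual_assignment(lab, 600))
    if (nrow(calls) > 0) n_called <- n_called + 1
  }
  expect_lte(n_called, 1) # zero calls in >= 95% of seeds
})

test_that("sparse windows yield no candidates", {
  peaks <- data.frame(chrom = "chr1", start = c(0, 5e6), end = c(500, 5e6 + 500))
  asg <- manual_assignment(c(1L, 1L), 2)
  expect_message(calls <- call_super_enhancers(peaks, asg), "no window")
  expect_equal(nrow(calls), 0L)
})
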