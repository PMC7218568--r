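test_that("count normalization follows its closed form", {
  fm <- tiny_fm(rbind(c(1, 0, 3), c(2, 0, 6)))
  norm <- normalize_counts(fm)
  expect_equal(as.numeric(norm[1, ]), c(log2(2501), 0, log2(7501)))
  expect_equal(as.numeric(norm[1, c(1, 3)]), c(11.2883, 12.8729),
               tolerance = 1e-5)
  # scale invariance: row 2 is row 1 scaled by 2
  expect_equal(as.numeric(norm[2, ]), as.numeric(norm[1, ]))
  # zeros stay exactly zero and all-zero rows stay all-zero
  z <- normalize_counts(tiny_fm(rbind(c(0, 0), c(1, 1))))
  expect_equal(as.numeric(z[1, ]), c(0, 0))
  expect_equal(length(z@x), 2L)
})

test_that("peak embedding is faithful, sign-fixed, and clips n_pcs", {
  set.seed(1)
  # duplicated peak triplets collapse to identical coordinates
  base <- matrix(rpois(20 * 2, 5), 20, 2)
  x <- cbind(base[, c(1, 1, 1)], base[, c(2, 2, 2)])
  emb <- embed_peaks(normalize_counts(x), n_pcs = 3)
  expect_lt(max(dist(emb$coords[1:3, ])), 1e-8)
  expect_lt(max(dist(emb$coords[4:6, ])), 1e-8)

  # rank-1 matrix: PC1 explains all variance
  r1 <- outer(1:6, c(2, 4, 8, 1))
  emb1 <- suppressWarnings(embed_peaks(r1, n_pcs = 4))
  expect_gt(emb1$var_fraction[1], 1 - 1e-10)

  # completeness: all components reconstruct the centered matrix
  m <- matrix(rpois(5 * 7, 4), 5, 7)
  embf <- embed_peaks(m, n_pcs = 5)
  centered <- sweep(m, 2, colMeans(m))
  expect_equal(embf$basis %*% t(embf$coords), centered,
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_warning(embed_peaks(m, n_pcs = 50), "clipped")
  # deterministic across repeated calls
  expect_identical(embed_peaks(m, 3)$coords, embed_peaks(m, 3)$coords)
})

test_that("peak KNN graph is symmetric with index tie-breaks", {
  # 3 collinear points, k = 1: middle point is everyone's neighbor
  emb <- structure(list(coords = cbind(c(0, 1, 2)), n_pcs = 1),
                   class = "peak_embedding")
  g <- build_peak_graph(emb, k = 1)
  a <- as.matrix(g$adjacency)
  expect_equal(sum(a) / 2, 2) # 2 undirected edges
  expect_equal(a, t(a))
  expect_equal(diag(a), rep(0, 3), ignore_attr = TRUE)

  # duplicated points are mutual nearest neighbors
  emb2 <- structure(list(coords = cbind(c(0, 0, 5, 5)), n_pcs = 1),
                    class = "peak_embedding")
  a2 <- as.matrix(build_peak_graph(emb2, k = 1)$adjacency)
  expect_equal(a2[1, 2], 1)
  expect_equal(a2[3, 4], 1)
  expect_equal(a2[1, 3], 0)

  # symmetry holds for arbitrary inputs
  set.seed(7)
  emb3 <- structure(list(coords = matrix(rnorm(40), 20, 2), n_pcs = 2),
                    class = "peak_embedding")
  a3 <- build_peak_graph(emb3, k = 4)$adjacency
  expect_equal(as.matrix(a3), t(as.matrix(a3)))

  expect_error(build_peak_graph(emb, k = 3), "smaller")
})

test_that("constrained Ward grouping recovers planted peak blocks", {
  # n_accessons = n_peaks: identity partition
  set.seed(3)
  emb <- structure(list(coords = matrix(rnorm(24), 12, 2), n_pcs = 2),
                   class = "peak_embedding")
  g <- build_peak_graph(emb, k = 3)
  idt <- group_peaks(emb, g, n_accessons = 12)
  expect_equal(idt$labels, 1:12)

  # two anti-correlated planted blocks, no noise: exact recovery
  n_half <- 50
  open1 <- rep(c(5, 0), each = 10)
  open2 <- rep(c(0, 5), each = 10)
  counts <- cbind(matrix(open1, 20, n_half), matrix(open2, 20, n_half))
  embp <- embed_peaks(normalize_counts(counts), n_pcs = 5)
  gp <- build_peak_graph(embp, k = 10)
  asg <- group_peaks(embp, gp, n_accessons = 2)
  truth <- rep(1:2, each = n_half)
  expect_equal(adjusted_rand_index(truth, asg$labels), 1)

  # two disconnected graph components force themselves as the clusters
  embd <- structure(list(coords = cbind(c(0, 1, 100, 101)), n_pcs = 1),
                    class = "peak_embedding")
  gd <- build_peak_graph(embd, k = 1)
  asgd <- group_peaks(embd, gd, n_accessons = 2)
  expect_equal(asgd$labels, c(1, 1, 2, 2))
  # requesting fewer clusters than components warns and returns components
  expect_warning(group_peaks(embd, gd, n_accessons = 1),
                 "connected components")
})

test_that("accesson matrix sums raw counts and normalizes rows", {
  fm <- tiny_fm(rbind(c(2, 3, 5), c(1, 1, 2)))
  asg <- manual_assignment(c(1, 1, 2))
  M <- build_accesson_matrix(fm, asg, method = "probability")
  expect_equal(unname(M$raw), rbind(c(5, 5), c(2, 2)))
  expect_equal(unname(M$normalized), rbind(c(0.5, 0.5), c(0.5, 0.5)))

  # z-score closed form with population SD
  Mz <- build_accesson_matrix(tiny_fm(matrix(c(1, 2, 3), 1)),
                              manual_assignment(1:3), method = "zscore")
  expect_equal(unname(round(Mz$normalized, 5)),
               matrix(c(-1.22474, 0, 1.22474), 1))

  # constant rows z-score to zero; zero rows stay zero in probability
  Mc <- build_accesson_matrix(tiny_fm(rbind(c(2, 2), c(0, 0))),
                              manual_assignment(1:2), method = "zscore")
  expect_equal(unname(Mc$normalized), matrix(0, 2, 2))
  Mp <- build_accesson_matrix(tiny_fm(rbind(c(2, 2), c(0, 0))),
                              manual_assignment(1:2), method = "probability")
  expect_equal(unname(Mp$normalized[2, ]), c(0, 0))
})

test_that("accesson construction conserves counts and partitions peaks", {
  set.seed(11)
  for (rep in 1:5) {
    counts <- random_counts(15, 40, density = 0.3)
    norm <- normalize_counts(counts)
    emb <- suppressWarnings(embed_peaks(norm, n_pcs = 10))
    g <- build_peak_graph(emb, k = 5)
    asg <- suppressWarnings(group_peaks(emb, g, n_accessons = 8))
    # total partition: every peak assigned exactly once
    expect_equal(length(asg$labels), 40L)
    expect_true(all(asg$labels >= 1 & asg$labels <= asg$n_accessons))
    expect_true(all(tabulate(asg$labels, asg$n_accessons) > 0))
    # conservation: per-cell accesson row sums equal count row sums exactly
    M <- build_accesson_matrix(counts, asg)
    expect_identical(unname(rowSums(M$raw)), unname(rowSums(counts)))
  }
})

test_that("accesson assignment is deterministic given identical inputs", {
  sim <- generate_dataset(small_config(seed = 9))
  norm <- normalize_counts(sim$data)
  emb <- embed_peaks(norm, n_pcs = 20)
  g <- build_peak_graph(emb, k = 10)
  a1 <- group_peaks(emb, g, n_accessons = 30)
  a2 <- group_peaks(emb, g, n_accessons = 30)
  expect_identical(a1$labels, a2$labels)
})
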