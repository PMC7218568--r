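test_that("MTX round trip preserves the stored triples in both orientations", {
  counts <- matrix(0, 3, 4)
  counts[cbind(c(1, 1, 2, 3, 3), c(1, 3, 2, 1, 4))] <- c(2, 1, 5, 3, 4)
  fm <- tiny_fm(counts)
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("m.mtx", "p.bed", "b.txt"))
  write_fragment_matrix(fm, paths[1], paths[2], paths[3])

  back <- read_fragment_matrix(paths[1], paths[2], paths[3])
  expect_equal(as.matrix(back$counts), counts, ignore_attr = TRUE)
  expect_equal(back$barcodes, fm$barcodes)
  expect_equal(back$peaks, fm$peaks)
  expect_equal(length(back$counts@x), 5L)

  # peaks x cells storage resolves to the identical matrix
  Matrix::writeMM(Matrix::t(fm$counts), paths[1])
  back2 <- read_fragment_matrix(paths[1], paths[2], paths[3])
  expect_equal(as.matrix(back2$counts), counts, ignore_attr = TRUE)

  # second write produces byte-identical files
  write_fragment_matrix(fm, paths[1], paths[2], paths[3])
  first <- readLines(paths[1])
  write_fragment_matrix(fm, file.path(dir, "m2.mtx"), paths[2], paths[3])
  expect_identical(readLines(file.path(dir, "m2.mtx")), first)
})

test_that("mismatched or invalid inputs are rejected", {
  counts <- matrix(1, 3, 4)
  fm <- tiny_fm(counts)
  dir <- withr::local_tempdir()
  paths <- file.path(dir, c("m.mtx", "p.bed", "b.txt"))
  write_fragment_matrix(fm, paths[1], paths[2], paths[3])

  writeLines(sprintf("bc%03d", 1:5), paths[3]) # 5 barcodes, 3x4 matrix
  expect_error(read_fragment_matrix(paths[1], paths[2], paths[3]),
               "neither orientation")
  expect_error(read_fragment_matrix("does-not-exist.mtx", paths[2], paths[3]),
               "not found")

  expect_error(fragment_matrix(matrix(-1, 2, 2), c("a", "b"),
                               data.frame(chrom = "chr1", start = c(0, 10),
                                          end = c(5, 15))),
               "non-negative")
  expect_error(fragment_matrix(matrix(0.5, 2, 2), c("a", "b"),
                               data.frame(chrom = "chr1", start = c(0, 10),
                                          end = c(5, 15))),
               "integral")
  expect_error(fragment_matrix(matrix(1, 2, 2), c("a", "a"),
                               data.frame(chrom = "chr1", start = c(0, 10),
                                          end = c(5, 15))),
               "duplicate")
  expect_error(tiny_fm(matrix(1, 2, 2), start = c(10, 20), width = -5),
               "start < end")

  # square matrix requires an explicit orientation
  fm2 <- tiny_fm(matrix(1, 3, 3))
  write_fragment_matrix(fm2, paths[1], paths[2], paths[3])
  expect_error(read_fragment_matrix(paths[1], paths[2], paths[3]),
               "ambiguous")
  expect_silent(read_fragment_matrix(paths[1], paths[2], paths[3],
                                     orientation = "cells"))
})

test_that("per-cell QC metrics follow their definitions", {
  counts <- rbind(c(500, 300), c(10, 0))
  fm <- tiny_fm(counts)
  qc <- compute_cell_qc(fm, totals = c(1000, 40))
  expect_equal(qc$n_fragments, c(1000, 40))
  expect_equal(qc$frac_in_peaks, c(0.8, 0.25))

  # totals absent: in-peak sums are the totals and the fraction is 1
  qc0 <- compute_cell_qc(fm)
  expect_equal(qc0$n_fragments, c(800, 10))
  expect_equal(qc0$frac_in_peaks, c(1, 1))

  expect_error(compute_cell_qc(fm, totals = c(700, 40)), "smaller")
})

test_that("TSS fraction counts reads in peaks intersecting the TSS window", {
  # peak 1 at [1000, 1500) intersects the [1000, 5000) window of a TSS at
  # 3000; peak 2 at [6000, 6500) does not; peak 3 is on another chromosome
  fm <- tiny_fm(rbind(c(4, 6, 10), c(0, 2, 0)),
                chrom = c("chr1", "chr1", "chr2"),
                start = c(1000, 6000, 1000))
  tss <- data.frame(gene = "g1", chrom = "chr1", tss = 3000, strand = "+")
  qc <- compute_cell_qc(fm, tss = tss, tss_window = 2000)
  expect_equal(qc$frac_tss, c(4 / 20, 0))

  # a peak starting exactly at the half-open window end is excluded
  fm2 <- tiny_fm(matrix(c(3, 5), 1), chrom = c("chr1", "chr1"),
                 start = c(5000, 4999))
  qc2 <- compute_cell_qc(fm2, tss = tss, tss_window = 2000)
  expect_equal(qc2$frac_tss, 5 / 8)
})

test_that("cell filtering applies strict cutoffs and errors when empty", {
  counts <- matrix(5, 4, 3)
  fm <- tiny_fm(counts)
  qc <- data.frame(barcode = fm$barcodes,
                   n_fragments = c(3000, 3000, 1500, 500),
                   frac_in_peaks = c(0.25, 0.15, 0.25, 0.05))
  kept <- filter_cells(fm, qc, pf_cutoff = 0.2, nf_cutoff = 2000)
  expect_equal(kept$barcodes, fm$barcodes[1])

  all_kept <- filter_cells(fm, qc, pf_cutoff = 0, nf_cutoff = 0)
  expect_equal(all_kept$barcodes, fm$barcodes)
  expect_equal(as.matrix(all_kept$counts), as.matrix(fm$counts))

  expect_error(filter_cells(fm, qc, pf_cutoff = 1.0, nf_cutoff = 1e9),
               "no cells pass")
})

test_that("peak filtering thresholds qscores with file-order tie-breaks", {
  fm <- tiny_fm(matrix(1:12, 4, 3), qscore = c(40, 30, 36))
  kept <- filter_peaks(fm, min_qscore = 35)
  expect_equal(kept$peaks$qscore, c(40, 36))
  expect_equal(as.matrix(kept$counts), as.matrix(fm$counts)[, c(1, 3)],
               ignore_attr = TRUE)

  expect_equal(filter_peaks(fm, min_qscore = 0)$peaks, fm$peaks)

  tied <- tiny_fm(matrix(1, 2, 3), qscore = c(10, 10, 9))
  expect_equal(filter_peaks(tied, max_peaks = 2)$peaks$qscore, c(10, 10))

  noq <- tiny_fm(matrix(1, 2, 3))
  expect_error(filter_peaks(noq, min_qscore = 5), "qscore column absent")
})

test_that("cell and peak filters commute when QC is supplied externally", {
  set.seed(42)
  fm <- tiny_fm(random_counts(8, 10), qscore = runif(10, 5, 50))
  qc <- data.frame(barcode = fm$barcodes,
                   n_fragments = sample(500:4000, 8),
                   frac_in_peaks = runif(8))
  a <- filter_peaks(filter_cells(fm, qc, 0.3, 1500), min_qscore = 20)
  b <- filter_cells(filter_peaks(fm, min_qscore = 20), qc, 0.3, 1500)
  expect_equal(a$barcodes, b$barcodes)
  expect_equal(a$peaks, b$peaks)
  expect_equal(as.matrix(a$counts), as.matrix(b$counts))
  # filtering peaks never changes a retained cell's count in a retained peak
  expect_equal(as.matrix(a$counts),
               as.matrix(fm$counts)[fm$barcodes %in% a$barcodes,
                                    fm$peaks$qscore >= 20],
               ignore_attr = TRUE)
})
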