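make_toy <- function(ints, labels = NULL, mz = NULL) {
  n <- nrow(ints)
  if (is.null(labels)) labels <- rep("A", n)
  cores <- data.frame(core_id = unique(labels), label = unique(labels))
  if (is.null(mz)) mz <- seq_len(ncol(ints))
  msi_dataset(ints, data.frame(x = seq_len(n) - 1, y = 0, core_id = labels),
              cores, mz = mz)
}

test_that("min-max normalization maps each pixel onto [0,1] and is idempotent", {
  d <- make_toy(rbind(c(2, 4, 6), c(5, 5, 5), c(0, 1, 3)))
  out <- normalize_minmax(d)
  expect_equal(out$intensities[1, ], c(0, 0.5, 1))
  expect_equal(out$intensities[2, ], c(0, 0, 0))  # constant -> zeros
  expect_true(all(out$intensities >= 0 & out$intensities <= 1))
  # postcondition: min 0 and (max 1 or all zero)
  for (i in 1:3) {
    v <- out$intensities[i, ]
    expect_equal(min(v), 0)
    expect_true(max(v) == 1 || all(v == 0))
  }
  again <- normalize_minmax(out)
  expect_equal(again$intensities, out$intensities)
})

test_that("off-tissue masking removes flagged pixels but keeps matrix cores", {
  n <- 10
  px <- data.frame(x = 0:(n - 1), y = 0,
                   core_id = c(rep("t1", 6), rep("m1", 4)),
                   tissue = c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0))
  cores <- data.frame(core_id = c("t1", "m1"), label = c("AdCy", "Matrix"))
  d <- msi_dataset(matrix(runif(n * 4), n, 4), px, cores, mz = 1:4)
  out <- mask_off_tissue(d, matrix_class = "Matrix")
  # tissue core keeps its 3 tissue pixels; matrix core keeps all 4
  expect_equal(sum(out$pixels$core_id == "t1"), 3)
  expect_equal(sum(out$pixels$core_id == "m1"), 4)
})

test_that("a tissue core with an all-zero mask empties with a warning", {
  px <- data.frame(x = 0:3, y = 0, core_id = rep("t1", 4), tissue = 0L)
  cores <- data.frame(core_id = "t1", label = "AdCy")
  d <- msi_dataset(matrix(1, 4, 2), px, cores, mz = 1:2)
  expect_warning(out <- mask_off_tissue(d, matrix_class = "Matrix"), "t1")
  expect_equal(nrow(out$intensities), 0)
})

test_that("matrix filter reproduces a brute-force Pearson ranking", {
  # 10 pixels, 3 peaks: A = reference, B strongly correlated, C independent
  set.seed(7)
  sc <- binning_scheme(100, 110, 0.1)
  amp_a <- 10 + 3 * rnorm(10)
  amp_b <- 2 + 0.5 * (amp_a - 10) + 0.01 * rnorm(10)
  amp_c <- 2 + abs(rnorm(10))
  centers <- bin_centers(sc)
  peak <- function(mz, h) sapply(centers, function(c0) {
    sum(h * exp(-(c0 - mz)^2 / (2 * 0.05^2)))
  })
  ints <- t(sapply(1:10, function(i) {
    peak(102, amp_a[i]) + peak(105, amp_b[i]) + peak(108, amp_c[i])
  }))
  d <- msi_dataset(ints, data.frame(x = 1:10, y = 1, core_id = "c1"),
                   data.frame(core_id = "c1", label = "T"),
                   mz = centers, scheme = sc)
  res <- matrix_filter(d, n_filter = 2, window = 0.2, matrix_class = NULL)

  # brute-force oracle: Pearson of every detected peak against the apex of A
  apex_a <- which.min(abs(centers - 102))
  peaks <- detect_peaks(d)
  brute <- sapply(peaks, function(p) cor(ints[, p], ints[, apex_a]))
  top2 <- centers[peaks[order(-brute)[1:2]]]
  expect_setequal(round(res$report$selected_peaks$mz, 1), round(top2, 1))
  expect_equal(res$report$reference_mz, centers[apex_a])

  # A and B zeroed everywhere, C untouched
  apex_b <- which.min(abs(centers - 105))
  apex_c <- which.min(abs(centers - 108))
  expect_true(all(res$dataset$intensities[, apex_a] == 0))
  expect_true(all(res$dataset$intensities[, apex_b] == 0))
  expect_equal(res$dataset$intensities[, apex_c], ints[, apex_c])
  # report sorted by descending correlation
  expect_false(is.unsorted(rev(res$report$selected_peaks$correlation)))
})

test_that("matrix filter saturates and is idempotent", {
  sim <- generate_tma(small_config(seed = 5L))
  d <- sim$dataset
  all_zeroed <- matrix_filter(d, n_filter = 10000L)
  peaks <- detect_peaks(d)
  expect_true(all(all_zeroed$dataset$intensities[, peaks] == 0))
  expect_equal(nrow(all_zeroed$report$selected_peaks), length(peaks))

  once <- matrix_filter(d, n_filter = 10L)
  filtered <- once$dataset$intensities
  for (i in seq_len(nrow(once$report$selected_peaks))) {
    m <- once$report$selected_peaks$mz[i]
    cols <- which(d$mz >= m - 0.02 & d$mz <= m + 0.02)
    expect_true(all(filtered[, cols] == 0))
  }
  # idempotence: re-zeroing the reported windows changes nothing
  rezero <- filtered
  for (i in seq_len(nrow(once$report$selected_peaks))) {
    m <- once$report$selected_peaks$mz[i]
    cols <- which(d$mz >= m - 0.02 & d$mz <= m + 0.02)
    rezero[, cols] <- 0
  }
  expect_identical(rezero, filtered)
})

test_that("matrix filter rejects degenerate reference intensities", {
  d <- make_toy(rbind(c(0, 50, 0, 1), c(0, 50, 0, 2), c(0, 50, 0, 3)))
  expect_error(matrix_filter(d, n_filter = 1), "constant")
})

test_that("preprocess_msi chains mask, filter and normalization", {
  sim <- generate_tma(small_config(seed = 9L))
  out <- preprocess_msi(sim$dataset, n_filter = 21L)
  expect_true(all(out$dataset$intensities >= 0 & out$dataset$intensities <= 1))
  expect_true(all(out$dataset$pixels$tissue == 1L |
                    pixel_labels(out$dataset) == "Matrix"))
  expect_s3_class(out$filter_report, "matrix_filter_report")
})
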