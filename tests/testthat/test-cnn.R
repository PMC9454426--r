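test_that("stratified folds preserve class ratios", {
  # 100 pixels per class, k = 5 -> exactly 20 per class per fold
  n <- 100
  labs <- rep(c("A", "B"), each = n)
  d <- msi_dataset(matrix(0, 2 * n, 3),
                   data.frame(x = seq_len(2 * n), y = 0, core_id = labs),
                   data.frame(core_id = c("A", "B"), label = c("A", "B")),
                   mz = 1:3)
  f <- stratified_folds(d, k = 5, seed = 1)
  expect_equal(sort(unique(f)), 0:4)
  tab <- table(pixel_labels(d), f)
  expect_true(all(tab == 20))

  # 101 pixels in one class -> fold sizes 20 or 21
  d2 <- msi_dataset(matrix(0, 201, 3),
                    data.frame(x = 1:201, y = 0,
                               core_id = c(labs, "A")[1:201]),
                    data.frame(core_id = c("A", "B"), label = c("A", "B")),
                    mz = 1:3)
  f2 <- stratified_folds(d2, k = 5, seed = 1)
  sizes <- table(pixel_labels(d2), f2)["A", ]
  expect_true(all(sizes %in% c(20, 21)))

  # determinism and the small-class error
  expect_identical(stratified_folds(d, 5, seed = 9),
                   stratified_folds(d, 5, seed = 9))
  d3 <- subset_pixels(d, 1:103)
  expect_error(stratified_folds(d3, k = 5), "B")
})

test_that("model construction validates lengths and is seed-deterministic", {
  a <- small_arch(3L)
  m1 <- build_model(a, 1000L, c("x", "y", "z"), seed = 4L)
  m2 <- build_model(a, 1000L, c("x", "y", "z"), seed = 4L)
  expect_identical(m1$weights$conv_w, m2$weights$conv_w)
  expect_identical(m1$weights$fc_w, m2$weights$fc_w)
  m3 <- build_model(a, 1000L, c("x", "y", "z"), seed = 5L)
  expect_false(identical(m1$weights$fc_w, m3$weights$fc_w))

  # forward on a zero spectrum: finite scores, one per class
  s <- predict_scores(m1, numeric(1000))
  expect_equal(dim(s), c(1L, 3L))
  expect_true(all(is.finite(s)))

  # pooling that collapses the signal names the offending block
  deep <- arch_config(n_conv_blocks = 6L,
                      channels = c(4L, 4L, 4L, 4L, 4L, 4L),
                      kernel_size = 9L, pool_size = 4L, n_classes = 3L)
  expect_error(build_model(deep, 64L, c("x", "y", "z")), "block")
})

test_that("flatten length follows the conv/pool recursion on the padded axis", {
  a <- small_arch(3L)  # kernel 5, pool 4, 3 blocks
  m <- build_model(a, 1000L, c("x", "y", "z"))
  expect_gte(m$n_pad, 1000L)
  L <- m$n_pad
  for (i in 1:3) L <- (L - 5 + 1) %/% 4
  expect_equal(m$weights$flatten_len, 16L * L)
  # padding restores full receptive coverage of the real bins
  expect_gte(maldinet:::receptive_coverage(m$n_pad, 5L, 4L, 3L), 1000L)
  expect_lt(maldinet:::receptive_coverage(1000L, 5L, 4L, 3L), 1000L)
})

test_that("cross-validation predicts every pixel exactly once and learns a separable problem", {
  sim <- generate_tma(degenerate_config(seed = 13L))
  # the degenerate dataset has zero pixel-to-pixel variance, so the
  # correlation filter does not apply; mask and normalize only
  d <- normalize_minmax(mask_off_tissue(sim$dataset))
  cfg <- train_config(epochs = 25L, batch_size = 16L, k_folds = 5L, seed = 2L)
  cv <- train_cv(d, small_arch(length(d$class_order)), cfg)

  # CV bookkeeping: one held-out prediction per pixel
  expect_equal(nrow(cv$predictions), nrow(d$intensities))
  expect_equal(anyDuplicated(cv$predictions[c("x", "y")]), 0)
  expect_length(cv$models, 5)

  # perfectly separable data (nearest-centroid oracle confirms) -> 100%
  expect_equal(nearest_centroid_accuracy(d), 1)
  expect_equal(overall_accuracy(cv$predictions), 100)

  # beats the majority-class baseline
  lab <- pixel_labels(d)
  expect_gt(overall_accuracy(cv$predictions),
            100 * max(table(lab)) / length(lab))
})

test_that("training is reproducible for a fixed seed", {
  sim <- generate_tma(small_config(seed = 17L))
  prep <- preprocess_msi(sim$dataset, n_filter = 21L)
  cfg <- train_config(epochs = 3L, batch_size = 16L, k_folds = 3L, seed = 5L)
  a <- small_arch(length(prep$dataset$class_order))
  cv1 <- train_cv(prep$dataset, a, cfg)
  cv2 <- train_cv(prep$dataset, a, cfg)
  expect_identical(cv1$predictions, cv2$predictions)
})

test_that("per-class accuracy averages fold-wise accuracies", {
  preds <- data.frame(
    true = c(rep("A", 4), rep("B", 2)),
    pred = c("A", "A", "A", "B", "B", "B"),
    fold = c(0, 0, 0, 0, 0, 0))
  acc <- per_class_accuracy(preds)
  expect_equal(unname(acc["A"]), 75)   # 3 of 4 in a single fold
  expect_equal(unname(acc["B"]), 100)

  all_ok <- data.frame(true = rep(c("A", "B"), 3),
                       pred = rep(c("A", "B"), 3),
                       fold = rep(0:2, each = 2))
  expect_true(all(per_class_accuracy(all_ok) == 100))

  # permutation invariance of the record order
  shuffled <- preds[c(4, 2, 6, 1, 5, 3), ]
  expect_equal(per_class_accuracy(shuffled), acc)

  # fold-wise averaging: 100% and 50% folds average to 75
  two_folds <- data.frame(
    true = rep("A", 4), pred = c("A", "A", "A", "B"),
    fold = c(0, 0, 1, 1))
  expect_equal(unname(per_class_accuracy(two_folds)["A"]), 75)
})
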