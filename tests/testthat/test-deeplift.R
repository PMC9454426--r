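test_that("contributions satisfy summation-to-delta on random networks", {
  arch <- arch_config(n_conv_blocks = 2L, channels = c(3L, 5L),
                      kernel_size = 3L, pool_size = 2L, n_classes = 4L)
  m <- build_model(arch, 32L, c("a", "b", "c", "d"), seed = 5L)
  set.seed(101)
  dev <- replicate(100, {
    x <- runif(32); r <- runif(32)
    cl <- sample(m$class_order, 1)
    co <- deeplift_attribute(m, x, cl, reference = r)
    sx <- predict_scores(m, x)[1, cl]
    sr <- predict_scores(m, r)[1, cl]
    abs(sum(co) - (sx - sr)) / max(abs(sx - sr), 1)
  })
  expect_lt(max(dev), 1e-4)
})

test_that("a linear network reduces DeepLift to gradient times input", {
  # slope-1 activations and no pooling make the whole net linear
  arch <- arch_config(n_conv_blocks = 2L, channels = c(3L, 5L),
                      kernel_size = 3L, pool_size = 1L,
                      activation_slope = 1.0, n_classes = 4L)
  m <- build_model(arch, 32L, c("a", "b", "c", "d"), seed = 6L)
  set.seed(42)
  for (i in 1:5) {
    x <- runif(32)
    co <- deeplift_attribute(m, x, 3L)   # zero reference
    g <- input_gradient(m, x, 3L)
    expect_equal(co, g * x, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("degenerate inputs are handled without NaN", {
  arch <- arch_config(n_conv_blocks = 2L, channels = c(3L, 5L),
                      kernel_size = 3L, pool_size = 2L, n_classes = 4L)
  m <- build_model(arch, 32L, c("a", "b", "c", "d"), seed = 7L)
  x <- runif(32)
  co <- deeplift_attribute(m, x, 1L, reference = x)  # delta = 0 everywhere
  expect_equal(as.numeric(co), rep(0, 32))
  expect_error(deeplift_attribute(m, x[1:10], 1L), "length")
  expect_error(deeplift_attribute(m, x, 1L, reference = x[1:10]), "length")
  expect_error(deeplift_attribute(m, x, "nope"), "unknown class")
})

test_that("class attribution averages correctly classified held-out pixels", {
  sim <- generate_tma(small_config(seed = 19L))
  prep <- preprocess_msi(sim$dataset, n_filter = 21L)
  d <- prep$dataset
  cv <- train_cv(d, small_arch(length(d$class_order)),
                 train_config(epochs = 8L, batch_size = 16L, k_folds = 3L,
                              seed = 3L))
  att <- suppressWarnings(class_attribution(cv$models, d, cv$predictions))
  expect_equal(dim(att$contributions),
               c(length(d$class_order), ncol(d$intensities)))
  expect_true(all(is.finite(att$contributions)))

  # mean invariance: a single correctly classified pixel equals its own
  # deeplift vector through its fold's model
  cl <- "A"
  sel <- which(cv$predictions$true == cl & cv$predictions$pred == cl)[1]
  pr <- cv$predictions[sel, ]
  row <- which(d$pixels$x == pr$x & d$pixels$y == pr$y)
  one <- deeplift_attribute(cv$models[[pr$fold + 1]],
                            d$intensities[row, ], cl)
  one_preds <- cv$predictions[sel, , drop = FALSE]
  att1 <- suppressWarnings(class_attribution(cv$models, d, one_preds))
  expect_equal(att1$contributions[cl, ], as.numeric(one), tolerance = 1e-12)

  # duplicated pixel leaves the mean unchanged
  att2 <- suppressWarnings(
    class_attribution(cv$models, d, one_preds[c(1, 1), ]))
  expect_equal(att2$contributions[cl, ], att1$contributions[cl, ])
})

test_that("top-k extraction keeps positive scores, ordered, ties to lower m/z", {
  contrib <- rbind(A = c(0.5, -2, 3, 0), B = c(-1, -2, -3, -4))
  att <- structure(list(contributions = contrib, mz = c(10, 20, 30, 40),
                        n_pixels = c(A = 1L, B = 1L), reference = "zero"),
                   class = "attribution_result")
  tk <- top_k_masses(att, k = 2L)
  expect_equal(tk$A$mz, c(30, 10))
  expect_equal(tk$A$score, c(3, 0.5))
  expect_equal(nrow(tk$B), 0)          # all-negative -> empty list
  expect_error(top_k_masses(att, k = 0L), "k")

  # tie-break: equal scores resolved toward the lower mass
  att$contributions <- rbind(A = c(1, 2, 0.5, 2), B = c(0.1, 1, 0.2, 0.3))
  tk2 <- top_k_masses(att, k = 2L)
  expect_equal(tk2$A$mz, c(20, 40))
  expect_equal(tk2$A$score, c(2, 2))

  # adjacent bins of one rendered peak collapse onto their apex
  att$contributions <- rbind(A = c(0.2, 1, 3, 1.2, 0.2, 0, 0.5, 0.1),
                             B = rep(-1, 8))
  att$mz <- seq(10, by = 10, length.out = 8)
  att$n_pixels <- c(A = 1L, B = 1L)
  tk3 <- top_k_masses(att, k = 3L)
  expect_equal(tk3$A$mz, c(30, 70))   # one entry per peak, not per bin
})

test_that("eight populated classes with k = 10 pool to 80 masses", {
  set.seed(33)
  contrib <- matrix(runif(8 * 200, 0.01, 1), 8, 200,
                    dimnames = list(paste0("cl", 1:8), NULL))
  att <- structure(list(contributions = contrib,
                        mz = seq(600, by = 0.01, length.out = 200),
                        n_pixels = stats::setNames(rep(1L, 8), paste0("cl", 1:8)),
                        reference = "zero"),
                   class = "attribution_result")
  pooled <- pool_top_masses(top_k_masses(att, k = 10L))
  expect_equal(nrow(pooled), 80)
  expect_equal(as.integer(table(pooled$class)[paste0("cl", 1:8)]),
               rep(10L, 8))
})
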