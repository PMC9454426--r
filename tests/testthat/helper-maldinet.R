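# Shared fixtures and oracles for the maldinet test suite. Everything is
# generated in code; no binary fixtures.

# small synthetic TMA on a short axis: fast to generate and train on
small_config <- function(seed = 3L, ...) {
  args <- list(
    scheme = binning_scheme(590, 600, 0.01),
    cores_per_class = c(A = 3L, B = 3L, C = 3L, Matrix = 2L),
    matrix_class = "Matrix",
    pixels_per_core = 9L,
    markers_per_class = 3L,
    n_background_peaks = 5L,
    n_matrix_peaks = 20L,
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# fully deterministic config: no jitter, no noise, no off-tissue pixels
degenerate_config <- function(seed = 11L, ...) {
  small_config(seed = seed, marker_jitter = 0, background_jitter = 0,
               matrix_jitter = 0, satellite_cv = 0, noise_sigma = 0,
               off_tissue_fraction = 0, ...)
}

# small CNN sized for the 1000-bin test axis
small_arch <- function(n_classes) {
  arch_config(n_conv_blocks = 3L, channels = c(4L, 8L, 16L),
              kernel_size = 5L, pool_size = 4L, n_classes = n_classes)
}

# nearest-centroid classifier: the separability oracle for train_cv
nearest_centroid_accuracy <- function(dataset) {
  lab <- pixel_labels(dataset)
  cents <- t(vapply(sort(unique(lab)), function(cl) {
    colMeans(dataset$intensities[lab == cl, , drop = FALSE])
  }, numeric(ncol(dataset$intensities))))
  d2 <- outer(rowSums(dataset$intensities^2), rowSums(cents^2), "+") -
    2 * dataset$intensities %*% t(cents)
  pred <- rownames(cents)[max.col(-d2)]
  mean(pred == lab)
}

# mean silhouette coefficient over all points (euclidean)
mean_silhouette <- function(xy, labels) {
  D <- as.matrix(stats::dist(xy))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# one full default-scale pipeline run (the headline experiment), computed
# once and shared by the acceptance checks that refer to it
.acceptance_env <- new.env(parent = emptyenv())
acceptance_run <- function() {
  if (is.null(.acceptance_env$res)) {
    .acceptance_env$res <- run_tma_experiment(
      synthetic_config(seed = 7L), train = train_config(seed = 7L))
  }
  .acceptance_env$res
}

expect_msi_equal <- function(a, b, tol = 1e-6) {
  expect_true(isTRUE(msi_all_equal <- maldinet:::msi_all_equal(a, b, tol)),
              info = paste("datasets differ:", msi_all_equal))
}
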