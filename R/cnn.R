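#' CNN architecture configuration
#'
#' The classifier is a 1-D convolutional network: `n_conv_blocks` blocks
#' of \[convolution -> leaky ReLU -> max pooling\], then a single fully
#' connected layer producing one raw score per class. Convolutions are
#' "valid" (no padding); pooling drops any remainder positions.
#'
#' @param n_conv_blocks Number of conv+pool blocks (default 6).
#' @param channels Output channels per block; length `n_conv_blocks`.
#' @param kernel_size Convolution kernel width (taps).
#' @param pool_size Max-pooling width.
#' @param activation_slope Negative slope of the leaky ReLU.
#' @param n_classes Number of output classes.
#' @return An `arch_config` object.
#' @export
arch_config <- function(n_conv_blocks = 6L,
                        channels = c(8L, 16L, 32L, 64L, 128L, 128L),
                        kernel_size = 9L, pool_size = 4L,
                        activation_slope = 0.01, n_classes = 8L) {
  if (n_conv_blocks < 1) stop("arch_config: need at least one conv block")
  if (length(channels) != n_conv_blocks) {
    stop("arch_config: channels must have length n_conv_blocks")
  }
  structure(list(n_conv_blocks = as.integer(n_conv_blocks),
                 channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 activation_slope = activation_slope,
                 n_classes = as.integer(n_classes)),
            class = "arch_config")
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs Training epochs per fold (default 30).
#' @param batch_size Mini-batch size (default 64).
#' @param k_folds Number of stratified cross-validation folds (default 5).
#' @param seed Seed controlling weight init, shuffling and fold splits.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 30L,
                         batch_size = 64L, k_folds = 5L, seed = 7L) {
  if (learning_rate <= 0) stop("train_config: learning_rate must be > 0")
  if (k_folds < 2) stop("train_config: k_folds must be >= 2")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "train_config")
}

# rightmost input bin still covered by the final representation, given
# valid convolutions and remainder-dropping max pools
receptive_coverage <- function(n_bins, kernel, pool, blocks) {
  L <- n_bins
  Lconv <- integer(blocks); Lpool <- integer(blocks)
  for (l in seq_len(blocks)) {
    Lc <- L - kernel + 1
    if (Lc < 1) return(0L)
    Lp <- Lc %/% pool
    if (Lp < 1) return(0L)
    Lconv[l] <- Lc; Lpool[l] <- Lp; L <- Lp
  }
  r <- Lpool[blocks]
  for (l in rev(seq_len(blocks))) {
    r <- min(Lconv[l], pool * r)
    upper <- if (l > 1) Lpool[l - 1] else n_bins
    r <- min(upper, r + kernel - 1)
  }
  r
}

# smallest padded length whose receptive field covers every real bin;
# remainder-dropping pools would otherwise blind the net to the axis end
padded_n_bins <- function(arch, n_bins) {
  n_bins <- as.integer(n_bins)
  limit <- n_bins + 4L * arch$pool_size^arch$n_conv_blocks +
    arch$kernel_size * arch$n_conv_blocks
  for (N in n_bins:limit) {
    if (receptive_coverage(N, arch$kernel_size, arch$pool_size,
                           arch$n_conv_blocks) >= n_bins) {
      return(N)
    }
  }
  stop("build_model: no valid padded length found")  # unreachable
}

# spectra as columns, zero-padded on the high-mass side
pad_columns <- function(X, n_pad) {
  if (nrow(X) == n_pad) return(X)
  rbind(X, matrix(0, n_pad - nrow(X), ncol(X)))
}

#' Build an initialized model
#'
#' Validates the architecture against the spectrum length (every block
#' must leave at least one position) and draws He-scaled initial weights
#' from a seeded RNG, so two builds with the same seed are identical.
#'
#' Spectra are zero-padded on the high-mass side to the smallest length
#' whose receptive field covers every real bin; without padding, the
#' remainder positions dropped by each max-pool would make the top of
#' the mass axis invisible to the classifier (and to attribution).
#'
#' @param arch An [arch_config()].
#' @param n_bins Spectrum length the model will consume.
#' @param class_order Character vector of class names, fixing the order
#'   of the score vector.
#' @param seed Seed for weight initialization.
#' @return A `trained_model` object (here: initialized, untrained).
#' @export
build_model <- function(arch, n_bins, class_order, seed = 7L) {
  stopifnot(inherits(arch, "arch_config"))
  if (length(class_order) != arch$n_classes) {
    stop("build_model: class_order length must equal arch$n_classes")
  }
  # validate the unpadded length first so impossible configs error clearly
  invisible(cnn_init_cpp(as.integer(n_bins), arch$channels, arch$kernel_size,
                         arch$pool_size, arch$n_classes, 0L))
  n_pad <- padded_n_bins(arch, n_bins)
  w <- cnn_init_cpp(n_pad, arch$channels, arch$kernel_size,
                    arch$pool_size, arch$n_classes, as.integer(seed))
  structure(list(arch = arch, weights = w, class_order = as.character(class_order),
                 n_bins = as.integer(n_bins), n_pad = n_pad),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model> %d conv blocks (channels %s), kernel %d, pool %d, %d bins -> %d classes\n",
    x$arch$n_conv_blocks, paste(x$arch$channels, collapse = "/"),
    x$arch$kernel_size, x$arch$pool_size, x$n_bins, x$arch$n_classes))
  invisible(x)
}

#' Forward pass: class scores for spectra
#'
#' @param model A `trained_model`.
#' @param x Numeric matrix, `n_spectra x n_bins` (or a single spectrum).
#' @return Matrix `n_spectra x n_classes` of raw scores, columns named by
#'   `model$class_order`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_bins) {
    stop("predict_scores: spectra have ", ncol(x), " bins, model expects ",
         model$n_bins)
  }
  s <- cnn_forward_cpp(model$weights, pad_columns(t(x), model$n_pad),
                       model$arch$channels,
                       model$arch$kernel_size, model$arch$pool_size,
                       model$arch$activation_slope)
  s <- t(s)
  colnames(s) <- model$class_order
  s
}

#' Stratified fold assignment
#'
#' Within each class, pixels are randomly permuted (seeded) and dealt
#' round-robin into `k` folds, so per-class fold sizes differ by at most
#' one: the splits preserve the class ratio.
#'
#' @param dataset An [msi_dataset()].
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `0..k-1`, one per pixel.
#' @export
stratified_folds <- function(dataset, k = 5L, seed = 7L) {
  stopifnot(inherits(dataset, "msi_dataset"))
  lab <- pixel_labels(dataset)
  fold <- integer(length(lab))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      if (length(idx) < k) {
        stop("stratified_folds: class '", cl, "' has only ", length(idx),
             " pixels, fewer than k = ", k)
      }
      perm <- sample(idx)
      fold[perm] <- (seq_along(perm) - 1L) %% k
    }
  })
  fold
}

#' Train under stratified k-fold cross-validation
#'
#' For each fold, a fresh model is trained on the remaining folds by
#' minimizing softmax cross-entropy with Adam and evaluated on the
#' held-out fold, so every pixel receives exactly one held-out
#' prediction.
#'
#' @param dataset A preprocessed [msi_dataset()] (intensities in `[0,1]`).
#' @param arch An [arch_config()]; `n_classes` must match the dataset.
#' @param cfg A [train_config()].
#' @param folds Optional precomputed fold vector from
#'   [stratified_folds()]; by default computed with `cfg$k_folds` and
#'   `cfg$seed`.
#' @param verbose Print per-fold progress.
#' @return A list with `models` (one `trained_model` per fold) and
#'   `predictions`: a data frame with one row per pixel (`x`, `y`,
#'   `core_id`, `true`, `pred`, `fold`, and `score_<class>` columns).
#' @export
train_cv <- function(dataset, arch = NULL, cfg = train_config(),
                     folds = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "msi_dataset"), inherits(cfg, "train_config"))
  classes <- dataset$class_order
  if (is.null(arch)) arch <- arch_config(n_classes = length(classes))
  if (arch$n_classes != length(classes)) {
    stop("train_cv: arch$n_classes (", arch$n_classes,
         ") does not match dataset classes (", length(classes), ")")
  }
  lab <- pixel_labels(dataset)
  y <- match(lab, classes) - 1L
  if (is.null(folds)) folds <- stratified_folds(dataset, cfg$k_folds, cfg$seed)
  k <- length(unique(folds))
  Xt <- t(dataset$intensities)            # n_bins x n_pixels

  models <- vector("list", k)
  pred_rows <- vector("list", k)
  for (f in sort(unique(folds))) {
    tr <- which(folds != f)
    te <- which(folds == f)
    m <- build_model(arch, nrow(Xt), classes, seed = cfg$seed + f)
    t0 <- Sys.time()
    fit <- cnn_train_cpp(m$weights,
                         pad_columns(Xt[, tr, drop = FALSE], m$n_pad), y[tr],
                         arch$channels, arch$kernel_size, arch$pool_size,
                         arch$activation_slope, cfg$epochs, cfg$batch_size,
                         cfg$learning_rate, cfg$seed + f)
    m$weights <- fit[c("conv_w", "conv_b", "fc_w", "fc_b")]
    m$loss <- fit$loss
    models[[f + 1L]] <- m
    sc <- predict_scores(m, dataset$intensities[te, , drop = FALSE])
    pr <- data.frame(
      x = dataset$pixels$x[te], y = dataset$pixels$y[te],
      core_id = dataset$pixels$core_id[te],
      true = lab[te], pred = classes[max.col(sc, ties.method = "first")],
      fold = f, stringsAsFactors = FALSE
    )
    scd <- as.data.frame(sc)
    names(scd) <- paste0("score_", classes)
    pred_rows[[f + 1L]] <- cbind(pr, scd)
    if (verbose) {
      message(sprintf("fold %d: %d train / %d test, acc %.1f%% (%.1fs)",
                      f, length(tr), length(te),
                      100 * mean(pr$pred == pr$true),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  predictions <- do.call(rbind, pred_rows)
  rownames(predictions) <- NULL
  list(models = models, predictions = predictions)
}

#' Per-class held-out accuracy
#'
#' For each class, the percentage of its pixels predicted correctly is
#' computed per fold and then averaged over folds ("averaged on all test
#' sets"). A class absent from the predictions is reported as `NA`.
#'
#' @param preds Prediction data frame from [train_cv()].
#' @return Named numeric vector of per-class accuracies in percent.
#' @export
per_class_accuracy <- function(preds) {
  stopifnot(nrow(preds) > 0, all(c("true", "pred", "fold") %in% names(preds)))
  classes <- sort(unique(preds$true))
  out <- vapply(classes, function(cl) {
    rows <- preds[preds$true == cl, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    per_fold <- vapply(split(rows, rows$fold),
                       function(ff) 100 * mean(ff$pred == ff$true),
                       numeric(1))
    mean(per_fold)
  }, numeric(1))
  names(out) <- classes
  out
}

#' Overall held-out accuracy
#' @param preds Prediction data frame from [train_cv()].
#' @return Overall percentage of correctly classified pixels.
#' @export
overall_accuracy <- function(preds) 100 * mean(preds$pred == preds$true)
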