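#' DeepLift contributions of one spectrum
#'
#' Propagates DeepLift multipliers from the target class score back to
#' the input bins, relative to a reference spectrum. Linear and
#' convolutional layers pass multipliers through their weights; leaky
#' ReLU units use the rescale rule `m = (f(z) - f(z_ref)) / (z - z_ref)`
#' (falling back to the pointwise derivative when `|z - z_ref| < eps`);
#' each max-pool routes its multiplier to the argmax position of the
#' actual input, scaled so the pooled output delta is carried exactly.
#' Contributions therefore satisfy summation-to-delta:
#' `sum(contrib) == score(x) - score(ref)` up to float error.
#'
#' @param model A `trained_model`.
#' @param spectrum Numeric vector of length `model$n_bins`.
#' @param target_class Class name or index whose score is explained.
#' @param reference Baseline spectrum (default: all zeros, the
#'   "no signal" state under min-max normalization).
#' @param eps Degenerate-delta threshold for the rescale fallback.
#' @return Numeric vector of signed per-bin contributions, with
#'   attributes `score_x` and `score_ref`.
#' @export
deeplift_attribute <- function(model, spectrum, target_class,
                               reference = NULL, eps = 1e-7) {
  stopifnot(inherits(model, "trained_model"))
  if (length(spectrum) != model$n_bins) {
    stop("deeplift_attribute: spectrum length ", length(spectrum),
         ", model expects ", model$n_bins)
  }
  if (is.null(reference)) reference <- numeric(model$n_bins)
  if (length(reference) != model$n_bins) {
    stop("deeplift_attribute: reference length ", length(reference),
         ", model expects ", model$n_bins)
  }
  tc <- target_index(model, target_class)
  pad <- numeric(model$n_pad - model$n_bins)
  r <- cnn_backprop_input_cpp(model$weights, c(as.numeric(spectrum), pad),
                              c(as.numeric(reference), pad),
                              model$arch$channels,
                              model$arch$kernel_size, model$arch$pool_size,
                              model$arch$activation_slope, tc - 1L,
                              0L, eps)
  # padding bins carry zero delta, hence zero contribution; drop them
  structure(as.numeric(r$contrib)[seq_len(model$n_bins)],
            score_x = r$score_x, score_ref = r$score_ref)
}

#' Gradient of a class score with respect to the input
#'
#' Plain backpropagated input gradient, used as the closed-form check
#' that DeepLift collapses to gradient-times-input for linear networks.
#'
#' @inheritParams deeplift_attribute
#' @return Numeric vector `d score / d input`.
#' @export
input_gradient <- function(model, spectrum, target_class) {
  stopifnot(inherits(model, "trained_model"))
  tc <- target_index(model, target_class)
  pad <- numeric(model$n_pad - model$n_bins)
  r <- cnn_backprop_input_cpp(model$weights, c(as.numeric(spectrum), pad),
                              numeric(0), model$arch$channels,
                              model$arch$kernel_size, model$arch$pool_size,
                              model$arch$activation_slope, tc - 1L,
                              1L, 1e-7)
  as.numeric(r$multiplier)[seq_len(model$n_bins)]
}

target_index <- function(model, target_class) {
  if (is.character(target_class)) {
    tc <- match(target_class, model$class_order)
    if (is.na(tc)) stop("unknown class: ", target_class)
    tc
  } else {
    tc <- as.integer(target_class)
    if (tc < 1 || tc > length(model$class_order)) stop("class index out of range")
    tc
  }
}

#' Class-level DeepLift attribution across a cross-validated run
#'
#' For every class, averages the DeepLift contribution vectors of all
#' correctly classified held-out pixels of that class, each pixel
#' attributed through the model of its own fold, against the all-zero
#' reference. Restricting to correct pixels keeps confused spectra from
#' contaminating the class profile.
#'
#' @param models List of per-fold `trained_model`s from [train_cv()].
#' @param dataset The preprocessed [msi_dataset()] used for training.
#' @param preds Prediction data frame from [train_cv()].
#' @param eps Rescale fallback threshold.
#' @return An `attribution_result`: list with `contributions` (matrix,
#'   classes x bins), `mz` (bin centers), `n_pixels` (named count of
#'   pixels averaged per class) and `reference` (the baseline used).
#' @export
class_attribution <- function(models, dataset, preds, eps = 1e-7) {
  stopifnot(inherits(dataset, "msi_dataset"))
  classes <- dataset$class_order
  n_bins <- ncol(dataset$intensities)
  # preds rows correspond to pixels of `dataset`; match on coordinates
  key_d <- paste(dataset$pixels$x, dataset$pixels$y)
  key_p <- paste(preds$x, preds$y)
  row_of <- match(key_p, key_d)
  if (anyNA(row_of)) stop("class_attribution: predictions refer to unknown pixels")

  contrib <- matrix(0, length(classes), n_bins,
                    dimnames = list(classes, NULL))
  n_used <- stats::setNames(integer(length(classes)), classes)
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    sel <- which(preds$true == cl & preds$pred == cl)
    if (!length(sel)) {
      warning("class_attribution: no correctly classified pixels for class ",
              cl, "; attribution left empty")
      next
    }
    acc <- numeric(n_bins)
    for (i in sel) {
      m <- models[[preds$fold[i] + 1L]]
      acc <- acc + deeplift_attribute(m, dataset$intensities[row_of[i], ],
                                      cl, eps = eps)
    }
    contrib[ci, ] <- acc / length(sel)
    n_used[ci] <- length(sel)
  }
  structure(list(contributions = contrib, mz = dataset$mz,
                 n_pixels = n_used, reference = "zero"),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %d classes x %d bins (reference: %s)\n",
              nrow(x$contributions), ncol(x$contributions), x$reference))
  invisible(x)
}

#' Top-k masses with the highest positive contribution per class
#'
#' For each class, selects the `k` masses of largest strictly positive
#' DeepLift score, reported as bin-center m/z in descending score order
#' (ties broken toward lower m/z). A "mass" is a positive local maximum
#' of the class's contribution vector: a rendered peak spans several
#' adjacent bins that all score highly, and reporting each bin
#' separately would fill the list with copies of one feature (it is the
#' apex that identifies the mass). Classes with fewer than `k` positive
#' local maxima yield shorter lists.
#'
#' @param attr An `attribution_result` from [class_attribution()].
#' @param k Number of masses per class (default 10).
#' @return A `top_k_masses` object: named list of data frames with
#'   columns `rank`, `mz`, `score`.
#' @export
top_k_masses <- function(attr, k = 10L) {
  stopifnot(inherits(attr, "attribution_result"))
  if (k < 1) stop("top_k_masses: k must be >= 1")
  out <- lapply(rownames(attr$contributions), function(cl) {
    v <- attr$contributions[cl, ]
    n <- length(v)
    left <- c(TRUE, v[-1] > v[-n])        # edges count one-sided
    right <- c(v[-n] >= v[-1], TRUE)
    pos <- which(v > 0 & left & right)
    if (!length(pos)) {
      return(data.frame(rank = integer(0), mz = numeric(0),
                        score = numeric(0)))
    }
    ord <- pos[order(-v[pos], attr$mz[pos])]
    ord <- ord[seq_len(min(k, length(ord)))]
    data.frame(rank = seq_along(ord), mz = attr$mz[ord], score = v[ord])
  })
  names(out) <- rownames(attr$contributions)
  bw <- if (length(attr$mz) > 1) stats::median(diff(attr$mz)) else NA_real_
  structure(out, class = "top_k_masses", k = as.integer(k), bin_width = bw)
}

#' Pool a top-k mass table across classes
#' @param topk A `top_k_masses` object.
#' @return Data frame with columns `class`, `rank`, `mz`, `score`.
#' @export
pool_top_masses <- function(topk) {
  stopifnot(inherits(topk, "top_k_masses"))
  rows <- lapply(names(topk), function(cl) {
    if (!nrow(topk[[cl]])) return(NULL)
    cbind(class = cl, topk[[cl]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
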