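#' Correctness map of cross-validated predictions
#'
#' Renders the pixel grid with correctly classified pixels in green,
#' misclassified pixels in red and unimaged positions as background,
#' mirroring the usual held-out classification overview of a TMA.
#'
#' @param preds Prediction data frame from [train_cv()].
#' @param dataset The [msi_dataset()] the predictions refer to (fixes
#'   the grid extent).
#' @param path Optional PNG output path.
#' @return Invisibly, a character matrix (`"correct"`, `"wrong"`,
#'   `"background"`) with one cell per grid position, rows = y.
#' @export
classification_map <- function(preds, dataset, path = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  W <- max(dataset$pixels$x) + 1L
  H <- max(dataset$pixels$y) + 1L
  m <- matrix("background", H, W)
  ok <- preds$pred == preds$true
  m[cbind(preds$y + 1L, preds$x + 1L)] <- ifelse(ok, "correct", "wrong")
  if (!is.null(path)) {
    rgb <- array(0, dim = c(H, W, 3))
    rgb[, , 1][m == "wrong"] <- 1
    rgb[, , 2][m == "correct"] <- 0.8
    bg <- m == "background"
    for (k in 1:3) rgb[, , k][bg] <- 0.15
    png::writePNG(rgb, path)
  }
  invisible(m)
}

#' Core-level majority vote
#'
#' Assigns each core the most frequent predicted label over its pixels.
#' Ties are broken by the higher mean class score, then by class order.
#' A core is "correct" when its majority label equals its annotation.
#'
#' @param preds Prediction data frame from [train_cv()].
#' @param cores Core annotation data frame (`core_id`, `label`), e.g.
#'   `dataset$cores`.
#' @return A `core_vote_result`: data frame with one row per voted core
#'   (`core_id`, `label`, `majority`, `vote_fraction`, `correct`) and
#'   attribute `fraction_correct` (percent of cores voted correctly).
#' @export
core_majority_vote <- function(preds, cores) {
  stopifnot(all(c("core_id", "pred") %in% names(preds)))
  cores <- as.data.frame(cores)
  voted <- lapply(split(preds, preds$core_id), function(px) {
    tab <- table(px$pred)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      # tie: higher mean score, then lexicographic class order
      sc <- vapply(top, function(cl) {
        col <- paste0("score_", cl)
        if (col %in% names(px)) mean(px[[col]]) else -Inf
      }, numeric(1))
      top <- top[order(-sc, top)][1]
    }
    data.frame(core_id = px$core_id[1], majority = top,
               vote_fraction = as.numeric(max(tab)) / nrow(px),
               n_pixels = nrow(px), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, voted)
  rownames(out) <- NULL
  missing <- setdiff(cores$core_id, out$core_id)
  if (length(missing)) {
    warning("core_majority_vote: core(s) without predicted pixels excluded: ",
            paste(missing, collapse = ", "))
  }
  out$label <- cores$label[match(out$core_id, cores$core_id)]
  out$correct <- out$majority == out$label
  out <- out[c("core_id", "label", "majority", "vote_fraction", "n_pixels",
               "correct")]
  attr(out, "fraction_correct") <- 100 * mean(out$correct)
  class(out) <- c("core_vote_result", "data.frame")
  out
}

#' @export
print.core_vote_result <- function(x, ...) {
  cat(sprintf("<core_vote_result> %d cores, %.1f%% voted correctly\n",
              nrow(x), attr(x, "fraction_correct")))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Ion image at a mass window
#'
#' Sums, per pixel, the intensities of all bins whose half-open interval
#' intersects `[mz - window, mz + window]`, and renders the result on
#' the pixel grid with a relative (per-image maximum) intensity scale.
#'
#' @param dataset An [msi_dataset()].
#' @param mz Center mass (Da).
#' @param window Half-width of the window (Da); default 0.003 (3 mDa).
#' @param path Optional PNG output path (grayscale relative intensity).
#' @return A list with `values` (raw per-pixel sums, in pixel-table
#'   order), `relative` (values / max, zeros when the image is empty),
#'   `image` (numeric matrix on the grid, `NA` off-sample), and `bins`
#'   (the summed bin indices).
#' @export
ion_image <- function(dataset, mz, window = 0.003, path = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (is.null(dataset$scheme)) stop("ion_image: dataset has no binning scheme")
  sc <- dataset$scheme
  lo_edge <- sc$lo_mz + (seq_len(sc$n_bins) - 1) * sc$bin_width
  hi_edge <- lo_edge + sc$bin_width
  bins <- which(hi_edge > mz - window & lo_edge <= mz + window)
  if (!length(bins)) {
    stop(sprintf("ion_image: window [%.5f, %.5f] Da does not intersect the axis",
                 mz - window, mz + window))
  }
  vals <- rowSums(dataset$intensities[, bins, drop = FALSE])
  mx <- max(vals)
  rel <- if (mx > 0) vals / mx else vals
  W <- max(dataset$pixels$x) + 1L
  H <- max(dataset$pixels$y) + 1L
  img <- matrix(NA_real_, H, W)
  img[cbind(dataset$pixels$y + 1L, dataset$pixels$x + 1L)] <- rel
  if (!is.null(path)) {
    g <- img
    g[is.na(g)] <- 0
    png::writePNG(g, path)
  }
  list(values = vals, relative = rel, image = img, bins = bins)
}
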