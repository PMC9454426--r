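#' Re-bin raw spectra onto an equidistant m/z axis
#'
#' Each raw data point's intensity is added to the bin whose half-open
#' interval `[lo + i*w, lo + (i+1)*w)` contains its m/z; points outside
#' the scheme's range are dropped. Total in-range intensity is conserved
#' exactly (summation order aside).
#'
#' @param dataset An [msi_dataset()] with a raw (shared) m/z axis, e.g.
#'   from [read_imzml()]. The generator already returns binned data.
#' @param scheme Target [binning_scheme()].
#' @return A binned `msi_dataset` on the scheme's bin centers.
#' @export
rebin <- function(dataset, scheme) {
  stopifnot(inherits(dataset, "msi_dataset"), inherits(scheme, "binning_scheme"))
  if (is.unsorted(dataset$mz)) stop("rebin: m/z axis must be sorted ascending")
  bin <- mz_to_bin(scheme, dataset$mz)
  keep <- !is.na(bin)
  n_px <- nrow(dataset$intensities)
  if (!any(keep)) {
    out <- matrix(0, n_px, scheme$n_bins)
  } else {
    # indicator matrix raw-point -> bin; binned = raw %*% S
    S <- Matrix::sparseMatrix(i = which(keep), j = bin[keep], x = 1,
                              dims = c(length(bin), scheme$n_bins))
    out <- as.matrix(dataset$intensities %*% S)
  }
  msi_dataset(out, dataset$pixels, dataset$cores, mz = bin_centers(scheme),
              scheme = scheme, class_order = dataset$class_order)
}

#' Per-pixel min-max normalization
#'
#' Maps every pixel's spectrum affinely onto `[0, 1]`:
#' `v <- (v - min) / (max - min)`. A constant spectrum (max == min) maps
#' to all zeros rather than NaN, keeping downstream tensors finite. The
#' operation is idempotent.
#'
#' @param dataset An [msi_dataset()].
#' @return The normalized dataset.
#' @export
normalize_minmax <- function(dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  x <- dataset$intensities
  if (nrow(x)) {
    i <- seq_len(nrow(x))
    mins <- x[cbind(i, max.col(-x, ties.method = "first"))]
    maxs <- x[cbind(i, max.col(x, ties.method = "first"))]
    rng <- maxs - mins
    rng[rng == 0] <- 1          # constant spectra -> zeros after shift
    x <- (x - mins) / rng
  }
  dataset$intensities <- x
  dataset
}

#' Remove off-tissue pixels
#'
#' Drops every pixel flagged `tissue = 0`, except pixels belonging to
#' cores of the dedicated matrix-only class: those cores contain no
#' tissue by design and are retained as their own class.
#'
#' @param dataset An [msi_dataset()].
#' @param matrix_class Name of the matrix-only class whose pixels are
#'   kept regardless of the tissue flag; `NULL` to keep none.
#' @return The masked dataset (cores left without pixels are retained in
#'   the core table; a warning names tissue cores that lost all pixels).
#' @export
mask_off_tissue <- function(dataset, matrix_class = "Matrix") {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (is.null(dataset$pixels$tissue)) {
    stop("mask_off_tissue: dataset carries no tissue mask")
  }
  lab <- pixel_labels(dataset)
  keep <- dataset$pixels$tissue == 1L |
    (!is.null(matrix_class) & lab %in% matrix_class)
  emptied <- setdiff(
    dataset$pixels$core_id[!keep],
    dataset$pixels$core_id[keep]
  )
  if (length(emptied)) {
    warning("mask_off_tissue: core(s) left with no pixels: ",
            paste(emptied, collapse = ", "))
  }
  subset_pixels(dataset, keep)
}

#' Detect peaks in the dataset-mean spectrum
#'
#' A "peak" is a local maximum of the mean spectrum whose height exceeds
#' a robust noise floor, `median + 3 * MAD` of the mean spectrum.
#'
#' @param dataset An [msi_dataset()].
#' @return Integer vector of apex bin indices, ascending.
#' @export
detect_peaks <- function(dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  m <- colMeans(dataset$intensities)
  floor_ <- stats::median(m) + 3 * stats::mad(m)
  n <- length(m)
  if (n < 3) return(integer(0))
  core <- m[2:(n - 1)]
  is_peak <- core > m[1:(n - 2)] & core >= m[3:n] & core > floor_
  which(is_peak) + 1L
}

#' Matrix-peak correlation filter
#'
#' Removes the signal of the MALDI matrix: finds the peaks of the mean
#' spectrum, identifies the reference matrix peak (the most intense mean
#' peak over the matrix-only pixels, falling back to the globally most
#' intense peak when no matrix class exists), ranks all peaks by the
#' Pearson correlation of their apex-bin intensity with the reference's
#' across pixels, and zeroes every bin within `window` Da of the
#' `n_filter` best-correlated peak positions (the reference included) in
#' every pixel.
#'
#' Intended to run on pre-normalization intensities.
#'
#' @param dataset An [msi_dataset()] with at least 2 pixels.
#' @param n_filter Number of peaks to remove (default 500).
#' @param window Half-width (Da) of the zeroed interval around each
#'   selected peak (default 0.02).
#' @param matrix_class Class whose pixels define "pure matrix" signal.
#' @return A list with `dataset` (filtered) and `report` (class
#'   `matrix_filter_report`: `reference_mz`, `selected_peaks` data frame
#'   of `mz` and `correlation` sorted by descending correlation, and
#'   `zeroed_intervals` data frame of `lo`/`hi` bounds clipped to the
#'   axis).
#' @export
matrix_filter <- function(dataset, n_filter = 500L, window = 0.02,
                          matrix_class = "Matrix") {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (nrow(dataset$intensities) < 2) stop("matrix_filter: need >= 2 pixels")
  if (n_filter < 1) stop("matrix_filter: n_filter must be >= 1")
  peaks <- detect_peaks(dataset)
  if (!length(peaks)) stop("matrix_filter: no peaks detected")
  mz <- dataset$mz

  lab <- pixel_labels(dataset)
  mat_rows <- which(!is.null(matrix_class) & lab %in% matrix_class)
  ref_basis <- if (length(mat_rows)) {
    colMeans(dataset$intensities[mat_rows, , drop = FALSE])
  } else {
    colMeans(dataset$intensities)
  }
  ref_peak <- peaks[which.max(ref_basis[peaks])]

  ref_int <- dataset$intensities[, ref_peak]
  if (stats::sd(ref_int) == 0) {
    stop("matrix_filter: reference peak intensity is constant across pixels")
  }
  apex <- dataset$intensities[, peaks, drop = FALSE]
  sds <- apply(apex, 2, stats::sd)
  corr <- rep(-Inf, length(peaks))
  ok <- sds > 0
  corr[ok] <- as.numeric(stats::cor(apex[, ok, drop = FALSE], ref_int))
  corr[peaks == ref_peak] <- 1  # reference always included

  n_sel <- min(n_filter, length(peaks))
  sel <- order(corr, decreasing = TRUE)[seq_len(n_sel)]
  sel_mz <- mz[peaks[sel]]
  sel_corr <- corr[sel]

  zero_lo <- pmax(sel_mz - window, min(mz))
  zero_hi <- pmin(sel_mz + window, max(mz))
  x <- dataset$intensities
  for (i in seq_along(sel_mz)) {
    cols <- which(mz >= sel_mz[i] - window & mz <= sel_mz[i] + window)
    if (length(cols)) x[, cols] <- 0
  }
  dataset$intensities <- x

  report <- structure(
    list(reference_mz = mz[ref_peak],
         selected_peaks = data.frame(mz = sel_mz, correlation = sel_corr),
         zeroed_intervals = data.frame(lo = zero_lo, hi = zero_hi)),
    class = "matrix_filter_report"
  )
  list(dataset = dataset, report = report)
}

#' @export
print.matrix_filter_report <- function(x, ...) {
  cat(sprintf("<matrix_filter_report> reference %.5f Da, %d peaks zeroed\n",
              x$reference_mz, nrow(x$selected_peaks)))
  invisible(x)
}

#' Run the standard preprocessing chain
#'
#' Re-binning (skipped when the data are already on the target scheme),
#' off-tissue masking, matrix-peak correlation filtering, and per-pixel
#' min-max normalization, in that order, so the classifier always sees
#' masked, filtered spectra in `[0, 1]`.
#'
#' @param dataset An [msi_dataset()].
#' @param scheme Target [binning_scheme()]; `NULL` keeps the current axis.
#' @param n_filter,window Matrix-filter parameters (see [matrix_filter()]).
#' @param matrix_class Matrix-only class name; `NULL` if none.
#' @return A list with `dataset` (preprocessed) and `filter_report`.
#' @export
preprocess_msi <- function(dataset, scheme = NULL, n_filter = 500L,
                           window = 0.02, matrix_class = "Matrix") {
  if (!is.null(scheme) && !identical(dataset$scheme, scheme)) {
    dataset <- rebin(dataset, scheme)
  }
  dataset <- mask_off_tissue(dataset, matrix_class = matrix_class)
  flt <- matrix_filter(dataset, n_filter = n_filter, window = window,
                       matrix_class = matrix_class)
  dataset <- normalize_minmax(flt$dataset)
  list(dataset = dataset, filter_report = flt$report)
}
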