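#' Construct an MSI dataset
#'
#' The central container of the package: one spectrum per imaged pixel, all
#' on a common mass axis, plus the core annotations that carry the
#' class labels. Intensities are stored as a dense pixels-by-bins matrix.
#'
#' Coordinates are 0-based, `x` = grid column, `y` = grid row (imzML's
#' 1-based coordinates are shifted on read/write).
#'
#' @param intensities Numeric matrix, `n_pixels x n_bins`, non-negative.
#' @param pixels Data frame with one row per pixel: integer columns `x`,
#'   `y`, character `core_id`, and integer `tissue` (1 = tissue, 0 = bare
#'   matrix surface).
#' @param cores Data frame with columns `core_id` and `label`, one row per
#'   core.
#' @param mz Numeric vector of m/z values for the columns of
#'   `intensities` (bin centers when `scheme` is given, otherwise a raw
#'   instrument axis).
#' @param scheme Optional [binning_scheme()]; `NULL` for raw (unbinned)
#'   data straight from an imzML file.
#' @param class_order Character vector fixing the order of class labels;
#'   defaults to the sorted unique labels in `cores`.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(intensities, pixels, cores, mz, scheme = NULL,
                        class_order = NULL, validate = TRUE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  pixels <- as.data.frame(pixels, stringsAsFactors = FALSE)
  cores <- as.data.frame(cores, stringsAsFactors = FALSE)
  if (is.null(pixels$tissue)) pixels$tissue <- 1L
  pixels$x <- as.integer(pixels$x)
  pixels$y <- as.integer(pixels$y)
  pixels$tissue <- as.integer(pixels$tissue)
  pixels$core_id <- as.character(pixels$core_id)
  cores$core_id <- as.character(cores$core_id)
  cores$label <- as.character(cores$label)
  if (is.null(class_order)) class_order <- sort(unique(cores$label))
  d <- structure(
    list(intensities = intensities, pixels = pixels, cores = cores,
         mz = as.numeric(mz), scheme = scheme,
         class_order = as.character(class_order)),
    class = "msi_dataset"
  )
  if (validate) validate_msi_dataset(d)
  d
}

#' Validate the invariants of an MSI dataset
#'
#' Checks coordinate uniqueness, finite intensities, core/label
#' consistency, m/z axis length, and that the class order covers all
#' labels without duplicates. Called on every construction and load.
#'
#' @param d An `msi_dataset`.
#' @return `d`, invisibly; stops on the first violated invariant.
#' @export
validate_msi_dataset <- function(d) {
  stopifnot(inherits(d, "msi_dataset"))
  n <- nrow(d$intensities)
  if (nrow(d$pixels) != n) {
    stop("msi_dataset: pixels table and intensity matrix disagree on pixel count")
  }
  if (length(d$mz) != ncol(d$intensities)) {
    stop("msi_dataset: m/z axis length does not match intensity columns")
  }
  if (n > 0 && !all(is.finite(d$intensities))) {
    stop("msi_dataset: non-finite intensities")
  }
  if (anyDuplicated(d$pixels[c("x", "y")])) {
    stop("msi_dataset: duplicated pixel coordinates")
  }
  if (anyDuplicated(d$cores$core_id)) {
    stop("msi_dataset: a core_id appears twice in the core table")
  }
  unknown <- setdiff(d$pixels$core_id, d$cores$core_id)
  if (length(unknown)) {
    stop("msi_dataset: pixels reference unannotated core(s): ",
         paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(d$class_order)) {
    stop("msi_dataset: duplicated class in class_order")
  }
  bad <- setdiff(d$cores$label, d$class_order)
  if (length(bad)) {
    stop("msi_dataset: label(s) outside class_order: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(d$scheme) && d$scheme$n_bins != ncol(d$intensities)) {
    stop("msi_dataset: scheme n_bins does not match intensity columns")
  }
  invisible(d)
}

#' Per-pixel class labels of an MSI dataset
#' @param d An `msi_dataset`.
#' @return Character vector, one label per pixel (its core's label).
#' @export
pixel_labels <- function(d) {
  stopifnot(inherits(d, "msi_dataset"))
  lab <- d$cores$label[match(d$pixels$core_id, d$cores$core_id)]
  as.character(lab)
}

#' Subset an MSI dataset by pixel index
#' @param d An `msi_dataset`.
#' @param keep Integer or logical index into the pixels.
#' @param drop_cores Drop cores left with no pixels (default `FALSE`).
#' @return The subsetted `msi_dataset`.
#' @export
subset_pixels <- function(d, keep, drop_cores = FALSE) {
  stopifnot(inherits(d, "msi_dataset"))
  px <- d$pixels[keep, , drop = FALSE]
  rownames(px) <- NULL
  cores <- d$cores
  if (drop_cores) cores <- cores[cores$core_id %in% px$core_id, , drop = FALSE]
  msi_dataset(d$intensities[keep, , drop = FALSE], px, cores,
              mz = d$mz, scheme = d$scheme, class_order = d$class_order)
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d pixels, %d m/z bins, %d cores, %d classes\n",
              nrow(x$intensities), ncol(x$intensities), nrow(x$cores),
              length(x$class_order)))
  if (!is.null(x$scheme)) cat("  axis:", format(x$scheme), "\n")
  else cat("  axis: raw (unbinned)\n")
  cat("  classes:", paste(x$class_order, collapse = ", "), "\n")
  invisible(x)
}

#' Test two datasets for equality up to intensity tolerance
#' @param a,b `msi_dataset` objects.
#' @param tol Relative intensity tolerance.
#' @return `TRUE` or a character description of the first difference.
#' @keywords internal
msi_all_equal <- function(a, b, tol = 1e-6) {
  if (!identical(dim(a$intensities), dim(b$intensities))) return("dimensions differ")
  if (!isTRUE(all.equal(a$pixels[c("x", "y", "core_id")],
                        b$pixels[c("x", "y", "core_id")],
                        check.attributes = FALSE))) return("pixel tables differ")
  if (!isTRUE(all.equal(a$cores, b$cores, check.attributes = FALSE))) {
    return("core tables differ")
  }
  if (!isTRUE(all.equal(a$mz, b$mz, tolerance = tol))) return("m/z axes differ")
  if (!isTRUE(all.equal(a$intensities, b$intensities, tolerance = tol,
                        check.attributes = FALSE))) return("intensities differ")
  TRUE
}
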