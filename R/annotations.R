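#' Read core annotations (and optional per-pixel tissue mask)
#'
#' The core table is a TSV with header `core_id<TAB>label`, one row per
#' core; the mask is a TSV with header `x<TAB>y<TAB>core_id<TAB>tissue`
#' (`tissue` in 0/1), one row per pixel. Validation rejects a core with
#' two conflicting labels, a pixel claimed by two cores, and labels
#' outside a configured class list.
#'
#' @param core_path Path to the core-label TSV.
#' @param mask_path Optional path to the per-pixel mask TSV.
#' @param classes Optional allowed class names; labels outside the list
#'   are rejected.
#' @return A `core_annotations` object: list with `cores` (data frame),
#'   `mask` (data frame or `NULL`) and `classes`.
#' @export
read_annotations <- function(core_path, mask_path = NULL, classes = NULL) {
  cores <- utils::read.table(core_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!all(c("core_id", "label") %in% names(cores))) {
    stop("read_annotations: core table needs columns core_id and label")
  }
  dup <- unique(cores$core_id[duplicated(cores$core_id)])
  for (d in dup) {
    labs <- unique(cores$label[cores$core_id == d])
    if (length(labs) > 1) {
      stop("read_annotations: core '", d, "' has conflicting labels: ",
           paste(labs, collapse = ", "))
    }
  }
  cores <- cores[!duplicated(cores$core_id), c("core_id", "label")]
  rownames(cores) <- NULL
  if (is.null(classes)) classes <- sort(unique(cores$label))
  bad <- setdiff(cores$label, classes)
  if (length(bad)) {
    stop("read_annotations: unknown label(s): ", paste(bad, collapse = ", "))
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- utils::read.table(mask_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (!all(c("x", "y", "core_id", "tissue") %in% names(mask))) {
      stop("read_annotations: mask needs columns x, y, core_id, tissue")
    }
    key <- paste(mask$x, mask$y)
    if (anyDuplicated(key)) {
      clash <- key[duplicated(key)][1]
      stop("read_annotations: pixel (", clash, ") referenced by two cores")
    }
    unknown <- setdiff(mask$core_id, cores$core_id)
    if (length(unknown)) {
      stop("read_annotations: mask references unannotated core(s): ",
           paste(unknown, collapse = ", "))
    }
    mask$x <- as.integer(mask$x)
    mask$y <- as.integer(mask$y)
    mask$tissue <- as.integer(mask$tissue)
  }
  structure(list(cores = cores, mask = mask, classes = classes),
            class = "core_annotations")
}

#' Write a dataset's annotations as TSV
#'
#' @param dataset An [msi_dataset()].
#' @param core_path Output path for the core-label TSV.
#' @param mask_path Optional output path for the per-pixel mask TSV.
#' @return Invisibly, `core_path`.
#' @export
write_annotations <- function(dataset, core_path, mask_path = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  utils::write.table(dataset$cores, core_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(mask_path)) {
    utils::write.table(dataset$pixels[c("x", "y", "core_id", "tissue")],
                       mask_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(core_path)
}
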