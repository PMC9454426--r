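#' Serialize a matrix-filter report as JSON
#'
#' @param report A `matrix_filter_report` from [matrix_filter()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "matrix_filter_report"))
  jsonlite::write_json(
    list(reference_mz = report$reference_mz,
         selected_peaks = report$selected_peaks,
         zeroed_intervals = report$zeroed_intervals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write held-out predictions as TSV
#'
#' One row per pixel: coordinates, core, true and predicted label, fold
#' id and per-class scores.
#'
#' @param preds Prediction data frame from [train_cv()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(preds, path) {
  utils::write.table(preds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model checkpoint
#'
#' A single self-describing file embedding the architecture, the class
#' order and the weights, so a checkpoint can be reloaded and applied
#' without the original configuration.
#'
#' @param model A `trained_model`.
#' @param path File path (conventionally `.cnn`).
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(list(format = "maldinet-cnn", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "maldinet-cnn")) {
    stop("load_model: not a maldinet model checkpoint")
  }
  stopifnot(inherits(obj$model, "trained_model"))
  obj$model
}
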