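#' Run the full synthetic-TMA classification experiment
#'
#' Convenience wrapper chaining the whole pipeline on a synthetic TMA:
#' generation, preprocessing (off-tissue masking, matrix-peak filter,
#' min-max normalization), stratified k-fold CNN cross-validation,
#' per-class accuracy, core-level majority voting and (optionally)
#' DeepLift attribution with top-k mass extraction.
#'
#' @param config A [synthetic_config()].
#' @param arch An [arch_config()]; defaults to the 6-block network sized
#'   to the dataset's class count.
#' @param train A [train_config()].
#' @param n_filter,window Matrix-filter parameters.
#' @param k Top masses per class for the attribution stage.
#' @param attribution Run the DeepLift stage (default `TRUE`).
#' @param verbose Print fold progress.
#' @return A list: `truth`, `filter_report`, `dataset` (preprocessed),
#'   `models`, `predictions`, `per_class_accuracy` (named %, per fold
#'   averaged), `core_votes`, and when `attribution` is on:
#'   `attribution`, `top_masses`, `mass_list`.
#' @export
run_tma_experiment <- function(config = synthetic_config(),
                               arch = NULL, train = train_config(),
                               n_filter = 500L, window = 0.02, k = 10L,
                               attribution = TRUE, verbose = FALSE) {
  sim <- generate_tma(config)
  prep <- preprocess_msi(sim$dataset, n_filter = n_filter, window = window,
                         matrix_class = config$matrix_class)
  ds <- prep$dataset
  if (is.null(arch)) arch <- arch_config(n_classes = length(ds$class_order))
  cv <- train_cv(ds, arch, train, verbose = verbose)
  acc <- per_class_accuracy(cv$predictions)
  votes <- core_majority_vote(cv$predictions, ds$cores)
  out <- list(truth = sim$truth, filter_report = prep$filter_report,
              dataset = ds, models = cv$models,
              predictions = cv$predictions, per_class_accuracy = acc,
              core_votes = votes)
  if (attribution) {
    att <- class_attribution(cv$models, ds, cv$predictions)
    topk <- top_k_masses(att, k = k)
    out$attribution <- att
    out$top_masses <- topk
    out$mass_list <- dedup_filter(topk)
  }
  out
}
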