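#' Duplicate-mass artifact filter
#'
#' Pools the per-class top-k mass lists and separates masses that are
#' unique to a single class from masses appearing (within a tolerance of
#' one bin width) in more than one class's list. Shared masses behave
#' like measurement artifacts rather than class markers and are excluded
#' from downstream feature use.
#'
#' @param topk A `top_k_masses` object from [top_k_masses()].
#' @param tol Duplicate tolerance in Da; defaults to one bin width
#'   inferred from the attribution axis when available, and must be
#'   given otherwise.
#' @return A `mass_list`: list with `entries` (pooled data frame:
#'   `class`, `rank`, `mz`, `score`), `unique_masses` (numeric),
#'   `artifact_masses` (numeric), `n_entries`, `n_unique`.
#' @export
dedup_filter <- function(topk, tol = NULL) {
  stopifnot(inherits(topk, "top_k_masses"))
  entries <- pool_top_masses(topk)
  if (is.null(entries) || !nrow(entries)) stop("dedup_filter: empty mass list")
  if (is.null(tol)) {
    tol <- attr(topk, "bin_width")
    if (is.null(tol) || is.na(tol)) {
      stop("dedup_filter: bin width unknown; pass `tol` explicitly")
    }
    tol <- tol * (1 + 1e-9)
  }
  mz <- entries$mz
  cls <- entries$class
  # a mass is an artifact when some entry of another class lies within tol
  artifact <- vapply(seq_along(mz), function(i) {
    any(abs(mz - mz[i]) <= tol & cls != cls[i])
  }, logical(1))
  unique_masses <- sort(unique(mz[!artifact]))
  artifact_masses <- sort(unique(mz[artifact]))
  structure(list(entries = entries,
                 unique_masses = unique_masses,
                 artifact_masses = artifact_masses,
                 n_entries = nrow(entries),
                 n_unique = sum(!artifact),
                 tol = tol),
            class = "mass_list")
}

#' @export
print.mass_list <- function(x, ...) {
  cat(sprintf(
    "<mass_list> %d pooled entries: %d class-unique, %d duplicated (artifact) masses\n",
    x$n_entries, x$n_unique, length(x$artifact_masses)))
  invisible(x)
}

#' Density-preserving supervised 2-D embedding of selected masses
#'
#' Reduces every pixel to its intensities at the class-unique masses and
#' embeds the resulting feature vectors into 2-D with densMAP — the
#' density-preserving extension of UMAP — supervised by the class
#' labels. The embedding runs through the system's Python `umap-learn`
#' (seeded; deterministic for a fixed seed).
#'
#' @param dataset An [msi_dataset()] (preprocessed).
#' @param features A `mass_list` from [dedup_filter()], or a numeric
#'   vector of m/z positions.
#' @param labels Per-pixel class labels; default: core labels.
#' @param seed RNG seed passed to the embedder.
#' @param n_neighbors,min_dist,target_weight,dens_lambda densMAP/UMAP
#'   hyperparameters (supervision strength is `target_weight`).
#' @param supervised Use the labels to supervise the embedding.
#' @param html Optional path; when given, an interactive SVG/HTML
#'   scatter colored by class with per-core hover tooltips is written.
#' @param python Python interpreter to invoke.
#' @return Data frame with one row per pixel: `x2d`, `y2d`, `class`,
#'   `core_id`.
#' @export
embed_densmap <- function(dataset, features, labels = NULL, seed = 7L,
                          n_neighbors = 15L, min_dist = 0.1,
                          target_weight = 0.5, dens_lambda = 2.0,
                          supervised = TRUE, html = NULL,
                          python = Sys.which("python")) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (inherits(features, "mass_list")) features <- features$unique_masses
  if (!length(features)) stop("embed_densmap: need at least one feature mass")
  n <- nrow(dataset$intensities)
  if (n < 2) stop("embed_densmap: need at least 2 pixels")
  if (is.null(labels)) labels <- pixel_labels(dataset)
  stopifnot(length(labels) == n)

  cols <- feature_bins(dataset, features)
  X <- dataset$intensities[, cols, drop = FALSE]
  ycode <- match(labels, sort(unique(labels))) - 1L

  if (!nzchar(python)) stop("embed_densmap: no python interpreter found")
  td <- tempfile("densmap")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  utils::write.table(X, file.path(td, "X.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  writeLines(as.character(ycode), file.path(td, "y.txt"))
  script <- system.file("python", "densmap_embed.py", package = "maldinet")
  stopifnot(nzchar(script))
  args <- c(script, file.path(td, "X.tsv"), file.path(td, "y.txt"),
            file.path(td, "out.tsv"), as.character(seed),
            as.character(n_neighbors), as.character(min_dist),
            as.character(if (supervised) target_weight else -1),
            as.character(dens_lambda))
  status <- system2(python, args, stdout = file.path(td, "log.txt"),
                    stderr = file.path(td, "log.txt"))
  if (status != 0 || !file.exists(file.path(td, "out.tsv"))) {
    stop("embed_densmap: umap-learn call failed:\n",
         paste(readLines(file.path(td, "log.txt"), warn = FALSE),
               collapse = "\n"))
  }
  emb <- utils::read.table(file.path(td, "out.tsv"), sep = "\t")
  out <- data.frame(x2d = emb[[1]], y2d = emb[[2]], class = labels,
                    core_id = dataset$pixels$core_id,
                    stringsAsFactors = FALSE)
  if (!all(is.finite(out$x2d)) || !all(is.finite(out$y2d))) {
    stop("embed_densmap: non-finite embedding coordinates")
  }
  if (!is.null(html)) write_embedding_html(out, html)
  out
}

# bin indices closest to the requested feature masses
feature_bins <- function(dataset, mzs) {
  cols <- vapply(mzs, function(m) which.min(abs(dataset$mz - m)), integer(1))
  unique(cols)
}

# dependency-free interactive scatter: SVG with per-point hover tooltips
write_embedding_html <- function(emb, path) {
  cls <- sort(unique(emb$class))
  pal <- grDevices::hcl.colors(max(3, length(cls)), "Dark 3")[seq_along(cls)]
  col <- pal[match(emb$class, cls)]
  rx <- range(emb$x2d); ry <- range(emb$y2d)
  sx <- function(v) 20 + 760 * (v - rx[1]) / max(rx[2] - rx[1], 1e-12)
  sy <- function(v) 580 - 560 * (v - ry[1]) / max(ry[2] - ry[1], 1e-12)
  pts <- sprintf(
    '<circle cx="%.1f" cy="%.1f" r="3" fill="%s" fill-opacity="0.7"><title>%s | core %s</title></circle>',
    sx(emb$x2d), sy(emb$y2d), col, emb$class, emb$core_id)
  leg <- sprintf(
    '<circle cx="%d" cy="%d" r="5" fill="%s"/><text x="%d" y="%d" font-size="12">%s</text>',
    810, 30 + 20 * seq_along(cls), pal, 820, 34 + 20 * seq_along(cls), cls)
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>densMAP embedding</title></head><body>",
    "<h3>densMAP embedding (hover a point for its core)</h3>",
    '<svg width="950" height="600" style="border:1px solid #ccc">',
    pts, leg, "</svg></body></html>")
  writeLines(html, path)
  invisible(path)
}
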