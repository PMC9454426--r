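#' Configuration for the synthetic tissue-microarray generator
#'
#' Describes a synthetic TMA whose statistical structure mirrors what the
#' classification pipeline assumes about real MALDI imaging data: each
#' tissue class carries a small set of private marker masses; all tissue
#' shares a family of background peaks; every pixel carries the MALDI
#' matrix signal — one dominant reference peak plus many satellite peaks
#' whose intensities co-vary with it across pixels; some in-core pixels
#' hold no tissue and show matrix-only signal; one class of cores is a
#' bare matrix control with no tissue at all.
#'
#' The default core counts follow the study design of an 8-class salivary
#' gland carcinoma TMA: Acin 20, AdCy 24, Anos 8, Control 6, Matrix 4,
#' MuEp 16, SaDu 4, Sec 3 cores.
#'
#' @param scheme Shared [binning_scheme()]; default 590-800 Da at 10 mDa
#'   (21,000 bins), a desk-scale stand-in for a high-resolution axis.
#' @param cores_per_class Named integer vector, class -> number of cores.
#' @param matrix_class Name of the matrix-only (no tissue) class, or
#'   `NULL` if every class is a tissue class. Must be a name in
#'   `cores_per_class` when not `NULL`.
#' @param pixels_per_core Pixels per core; pixels occupy the
#'   `pixels_per_core` grid offsets closest to the core center (a disk).
#' @param markers_per_class Private marker masses planted per tissue class.
#' @param marker_intensity Mean marker peak height (relative units).
#' @param marker_jitter Multiplicative log-normal sigma of per-pixel
#'   marker heights.
#' @param n_background_peaks Peaks shared by all tissue classes.
#' @param background_intensity Mean background peak height.
#' @param background_jitter Multiplicative log-normal sigma of per-pixel
#'   background peak heights.
#' @param matrix_jitter Log-normal sigma of the per-pixel matrix
#'   reference amplitude.
#' @param satellite_cv Coefficient of variation of satellite peak
#'   heights around their mean.
#' @param n_matrix_peaks Total size of the matrix peak family: the
#'   reference peak plus `n_matrix_peaks - 1` satellites co-varying
#'   with it (default 500, so the default 500-peak correlation filter
#'   can capture the family exactly).
#' @param matrix_corr Target Pearson correlation between each satellite
#'   and the reference matrix peak across pixels.
#' @param matrix_intensity Mean height of the reference matrix peak; by
#'   construction the tallest feature of the mean spectrum.
#' @param satellite_intensity Mean height of matrix satellite peaks.
#' @param peak_sigma Gaussian peak width (Da) on the m/z axis.
#' @param noise_sigma Scale of the additive non-negative (half-normal)
#'   noise per bin.
#' @param off_tissue_fraction Fraction of each tissue core's pixels that
#'   carry matrix-only signal and are flagged `tissue = 0`.
#' @param min_mz_separation Minimum distance (Da) between any two planted
#'   peak positions; must exceed twice the matrix-filter window so that
#'   planted structure stays unambiguous under filtering.
#' @param isotope_satellite Also plant a +1 Da isotope peak at half
#'   height for each marker (off by default).
#' @param core_gap Empty pixels between neighbouring core bounding boxes.
#' @param seed RNG seed; identical seeds give identical datasets.
#' @return A `synthetic_config` object (validated list).
#' @export
synthetic_config <- function(scheme = binning_scheme(590, 800, 0.01),
                             cores_per_class = c(Acin = 20L, AdCy = 24L,
                                                 Anos = 8L, Control = 6L,
                                                 Matrix = 4L, MuEp = 16L,
                                                 SaDu = 4L, Sec = 3L),
                             matrix_class = "Matrix",
                             pixels_per_core = 9L,
                             markers_per_class = 5L,
                             marker_intensity = 1.0,
                             marker_jitter = 0.3,
                             n_background_peaks = 30L,
                             background_intensity = 0.5,
                             background_jitter = 0.2,
                             n_matrix_peaks = 500L,
                             matrix_corr = 0.9,
                             matrix_intensity = 3.0,
                             matrix_jitter = 0.4,
                             satellite_intensity = 0.6,
                             satellite_cv = 0.25,
                             peak_sigma = 0.02,
                             noise_sigma = 0.02,
                             off_tissue_fraction = 0.1,
                             min_mz_separation = 0.05,
                             isotope_satellite = FALSE,
                             core_gap = 2L,
                             seed = 7L) {
  cfg <- list(scheme = scheme, cores_per_class = cores_per_class,
              matrix_class = matrix_class,
              pixels_per_core = as.integer(pixels_per_core),
              markers_per_class = as.integer(markers_per_class),
              marker_intensity = marker_intensity,
              marker_jitter = marker_jitter,
              n_background_peaks = as.integer(n_background_peaks),
              background_intensity = background_intensity,
              background_jitter = background_jitter,
              n_matrix_peaks = as.integer(n_matrix_peaks),
              matrix_corr = matrix_corr,
              matrix_intensity = matrix_intensity,
              matrix_jitter = matrix_jitter,
              satellite_intensity = satellite_intensity,
              satellite_cv = satellite_cv,
              peak_sigma = peak_sigma, noise_sigma = noise_sigma,
              off_tissue_fraction = off_tissue_fraction,
              min_mz_separation = min_mz_separation,
              isotope_satellite = isTRUE(isotope_satellite),
              core_gap = as.integer(core_gap), seed = as.integer(seed))
  stopifnot(inherits(scheme, "binning_scheme"))
  if (is.null(names(cores_per_class)) || any(names(cores_per_class) == "")) {
    stop("synthetic_config: cores_per_class must be a named vector")
  }
  if (any(cores_per_class < 0)) stop("synthetic_config: negative core count")
  if (!is.null(matrix_class) && !matrix_class %in% names(cores_per_class)) {
    stop("synthetic_config: matrix_class not among the class names")
  }
  if (cfg$pixels_per_core < 1) stop("synthetic_config: pixels_per_core < 1")
  if (!(off_tissue_fraction >= 0 && off_tissue_fraction < 1)) {
    stop("synthetic_config: off_tissue_fraction must be in [0, 1)")
  }
  if (!(matrix_corr > 0 && matrix_corr <= 1)) {
    stop("synthetic_config: matrix_corr must be in (0, 1]")
  }
  if (min_mz_separation <= 0) stop("synthetic_config: min_mz_separation <= 0")
  if (cfg$n_matrix_peaks < 1) {
    stop("synthetic_config: n_matrix_peaks must be >= 1 (the reference peak)")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# grid offsets of the n pixels closest to a core center (disk-shaped core)
core_offsets <- function(n) {
  r <- 0
  repeat {
    r <- r + 1
    g <- expand.grid(dx = -r:r, dy = -r:r)
    if (nrow(g) >= n) {
      d <- g$dx^2 + g$dy^2
      o <- order(d, atan2(g$dy, g$dx))
      if (sum(d <= r^2) >= n) return(g[o[seq_len(n)], , drop = FALSE])
    }
  }
}

# sample n peak positions in [lo, hi] with pairwise separation > sep
sample_separated_mz <- function(n, lo, hi, sep) {
  if (n == 0) return(numeric(0))
  if (n * sep > 0.8 * (hi - lo)) {
    stop("cannot place ", n, " peaks with separation ", sep,
         " in [", lo, ", ", hi, "]")
  }
  out <- numeric(0)
  tries <- 0
  while (length(out) < n) {
    cand <- stats::runif(n, lo, hi)
    for (m in cand) {
      if (length(out) == n) break
      if (!length(out) || min(abs(out - m)) > sep) out <- c(out, m)
    }
    tries <- tries + 1
    if (tries > 2000) stop("peak placement failed: axis too crowded")
  }
  out
}

# standardized matrix amplitude; degenerate (jitter 0) maps to zeros
standardized_lognormal <- function(A, mu0, sdlog) {
  if (sdlog <= 0) return(rep(0, length(A)))
  muA <- mu0 * exp(sdlog^2 / 2)
  sdA <- muA * sqrt(exp(sdlog^2) - 1)
  (A - muA) / sdA
}

# sparse peak-rendering matrix: n_peaks x n_bins Gaussian profiles
peak_render_matrix <- function(mzs, scheme, sigma) {
  centers <- bin_centers(scheme)
  half <- 4 * sigma
  ii <- list(); jj <- list(); vv <- list()
  for (p in seq_along(mzs)) {
    j1 <- max(1L, mz_to_bin(scheme, mzs[p] - half))
    j2 <- mz_to_bin(scheme, mzs[p] + half)
    if (is.na(j1)) j1 <- 1L
    if (is.na(j2)) j2 <- if (mzs[p] + half >= scheme$hi_mz) scheme$n_bins else 1L
    j <- j1:j2
    ii[[p]] <- rep.int(p, length(j))
    jj[[p]] <- j
    vv[[p]] <- exp(-(centers[j] - mzs[p])^2 / (2 * sigma^2))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                       dims = c(length(mzs), scheme$n_bins))
}

#' Generate a synthetic TMA dataset with known ground truth
#'
#' Lays the configured cores out on a square grid, renders per-pixel
#' spectra as sums of Gaussian peaks on the binned axis, and returns both
#' the dataset and the planted-structure record used as the oracle in
#' feature-recovery tests.
#'
#' Signal model per tissue pixel: shared background peaks + the pixel's
#' class markers (log-normal per-pixel heights) + the matrix reference
#' peak with log-normal amplitude `A` + satellite peaks constructed to
#' have Pearson correlation `matrix_corr` with `A` across pixels +
#' half-normal additive noise. Off-tissue pixels and all pixels of the
#' matrix-only class carry matrix signal and noise only.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `dataset` (an [msi_dataset()]) and
#'   `truth` (class `marker_ground_truth`: `class_markers`, `matrix_mzs`,
#'   `background_mzs`, `reference_mz`).
#' @export
generate_tma <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_tma_impl(config))
}

generate_tma_impl <- function(cfg) {
  sc <- cfg$scheme
  classes <- names(cfg$cores_per_class)
  marker_classes <- setdiff(classes, cfg$matrix_class)

  # --- plant peak positions, mutually separated ------------------------
  margin <- 4 * cfg$peak_sigma + cfg$min_mz_separation
  n_mark <- length(marker_classes) * cfg$markers_per_class
  n_sat <- cfg$n_matrix_peaks - 1L
  n_all <- n_mark + cfg$n_background_peaks + cfg$n_matrix_peaks
  all_mz <- sample_separated_mz(n_all, sc$lo_mz + margin, sc$hi_mz - margin,
                                cfg$min_mz_separation)
  marker_mz <- all_mz[seq_len(n_mark)]
  background_mz <- all_mz[n_mark + seq_len(cfg$n_background_peaks)]
  matrix_mz <- all_mz[n_mark + cfg$n_background_peaks +
                        seq_len(cfg$n_matrix_peaks)]
  reference_mz <- matrix_mz[1L]
  satellite_mz <- matrix_mz[-1L]
  class_markers <- split(marker_mz,
                         rep(marker_classes, each = cfg$markers_per_class))
  class_markers <- class_markers[marker_classes]

  # --- core layout on a square grid ------------------------------------
  core_tab <- data.frame(
    core_id = sprintf("%s_%02d",
                      rep(classes, cfg$cores_per_class),
                      unlist(lapply(cfg$cores_per_class, seq_len))),
    label = rep(classes, cfg$cores_per_class),
    stringsAsFactors = FALSE
  )
  n_cores <- nrow(core_tab)
  offs <- core_offsets(cfg$pixels_per_core)
  r <- max(abs(c(offs$dx, offs$dy)))
  cell <- 2L * r + 1L + cfg$core_gap
  ncol_grid <- ceiling(sqrt(n_cores))
  core_order <- sample.int(n_cores)  # shuffle classes over the grid
  cx <- ((seq_len(n_cores) - 1L) %% ncol_grid) * cell + r
  cy <- ((seq_len(n_cores) - 1L) %/% ncol_grid) * cell + r

  pixels <- do.call(rbind, lapply(seq_len(n_cores), function(i) {
    k <- core_order[i]
    data.frame(x = cx[i] + offs$dx, y = cy[i] + offs$dy,
               core_id = core_tab$core_id[k], stringsAsFactors = FALSE)
  }))
  pixels$label <- core_tab$label[match(pixels$core_id, core_tab$core_id)]
  n_px <- nrow(pixels)

  # tissue flags: matrix-class cores have no tissue; tissue cores lose a
  # seeded off_tissue_fraction of their pixels to bare matrix surface
  pixels$tissue <- 1L
  is_matrix_px <- !is.null(cfg$matrix_class) & pixels$label %in% cfg$matrix_class
  pixels$tissue[is_matrix_px] <- 0L
  for (cid in core_tab$core_id[!core_tab$label %in% cfg$matrix_class]) {
    idx <- which(pixels$core_id == cid)
    n_off <- round(cfg$off_tissue_fraction * length(idx))
    if (n_off > 0) pixels$tissue[sample(idx, n_off)] <- 0L
  }

  # --- per-pixel peak heights ------------------------------------------
  n_peaks <- n_all
  H <- matrix(0, n_px, n_peaks)
  has_tissue <- pixels$tissue == 1L

  # markers: only tissue pixels of the owning class
  for (ci in seq_along(marker_classes)) {
    rows <- which(has_tissue & pixels$label == marker_classes[ci])
    cols <- (ci - 1L) * cfg$markers_per_class + seq_len(cfg$markers_per_class)
    if (length(rows)) {
      H[rows, cols] <- cfg$marker_intensity *
        exp(stats::rnorm(length(rows) * length(cols), 0, cfg$marker_jitter))
    }
  }
  # background: all tissue pixels
  bg_cols <- n_mark + seq_len(cfg$n_background_peaks)
  if (length(bg_cols) && any(has_tissue)) {
    H[has_tissue, bg_cols] <- cfg$background_intensity *
      exp(stats::rnorm(sum(has_tissue) * length(bg_cols), 0,
                       cfg$background_jitter))
  }
  # matrix: every pixel; satellites correlated with the reference amplitude
  ref_col <- n_mark + cfg$n_background_peaks + 1L
  A <- cfg$matrix_intensity * exp(stats::rnorm(n_px, 0, cfg$matrix_jitter))
  zA <- standardized_lognormal(A, cfg$matrix_intensity, cfg$matrix_jitter)
  H[, ref_col] <- A
  if (n_sat > 0) {
    rho <- cfg$matrix_corr
    eps <- if (cfg$satellite_cv > 0) {
      matrix(stats::rnorm(n_px * n_sat), n_px)
    } else {
      matrix(0, n_px, n_sat)
    }
    sat <- cfg$satellite_intensity *
      (1 + cfg$satellite_cv * (rho * zA + sqrt(1 - rho^2) * eps))
    H[, ref_col + seq_len(n_sat)] <- pmax(sat, 0)
  }

  peaks_mz <- all_mz
  if (cfg$isotope_satellite) {
    peaks_mz <- c(peaks_mz, marker_mz + 1.00335)
    H <- cbind(H, 0.5 * H[, seq_len(n_mark), drop = FALSE])
  }

  # --- render and add noise --------------------------------------------
  R <- peak_render_matrix(peaks_mz, sc, cfg$peak_sigma)
  intens <- as.matrix(H %*% R)
  if (cfg$noise_sigma > 0) {
    intens <- intens + abs(stats::rnorm(length(intens), 0, cfg$noise_sigma))
  }

  dataset <- msi_dataset(intens, pixels[c("x", "y", "core_id", "tissue")],
                         core_tab, mz = bin_centers(sc), scheme = sc,
                         class_order = sort(classes))
  truth <- structure(
    list(class_markers = class_markers, matrix_mzs = matrix_mz,
         background_mzs = background_mz, reference_mz = reference_mz),
    class = "marker_ground_truth"
  )
  attr(dataset, "synth_recipe") <- list(
    config = cfg, background_mz = background_mz, matrix_mz = matrix_mz
  )
  list(dataset = dataset, truth = truth)
}

#' Replace class-marker signal in part of a core (label-noise model)
#'
#' Emulates a mislabelled core: a fraction of the core's pixels lose
#' their class-marker peaks and are regenerated as marker-free tissue
#' (background + matrix + noise) while the core keeps its class label.
#' This reproduces the situation where healthy connective tissue inside
#' a tumor core inherits the tumor label.
#'
#' @param dataset An [msi_dataset()] produced by [generate_tma()].
#' @param core_id Core to modify.
#' @param fraction Fraction of the core's pixels to strip of markers.
#' @param seed Seed for the pixel choice and regenerated signal;
#'   defaults to the generator seed + 1.
#' @return The modified dataset; attribute `"noise_pixels"` holds the
#'   row indices of the regenerated pixels.
#' @export
plant_label_noise <- function(dataset, core_id, fraction, seed = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  recipe <- attr(dataset, "synth_recipe")
  if (is.null(recipe)) {
    stop("plant_label_noise: dataset was not produced by generate_tma()")
  }
  if (!(fraction >= 0 && fraction <= 1)) stop("fraction must be in [0, 1]")
  if (!core_id %in% dataset$cores$core_id) {
    stop("plant_label_noise: unknown core ", core_id)
  }
  cfg <- recipe$config
  if (is.null(seed)) seed <- cfg$seed + 1L
  idx <- which(dataset$pixels$core_id == core_id)
  n_mod <- round(fraction * length(idx))
  if (n_mod == 0) {
    attr(dataset, "noise_pixels") <- integer(0)
    return(dataset)
  }
  withr::with_seed(seed, {
    mod <- sort(sample(idx, n_mod))
    mzs <- c(recipe$background_mz, recipe$matrix_mz)
    Hm <- matrix(0, n_mod, length(mzs))
    nb <- length(recipe$background_mz)
    if (nb > 0) {
      Hm[, seq_len(nb)] <- cfg$background_intensity *
        exp(stats::rnorm(n_mod * nb, 0, cfg$background_jitter))
    }
    A <- cfg$matrix_intensity * exp(stats::rnorm(n_mod, 0, cfg$matrix_jitter))
    zA <- standardized_lognormal(A, cfg$matrix_intensity, cfg$matrix_jitter)
    Hm[, nb + 1L] <- A
    nsat <- length(recipe$matrix_mz) - 1L
    if (nsat > 0) {
      rho <- cfg$matrix_corr
      eps <- matrix(stats::rnorm(n_mod * nsat), n_mod)
      sat <- cfg$satellite_intensity *
        (1 + cfg$satellite_cv * (rho * zA + sqrt(1 - rho^2) * eps))
      Hm[, nb + 1L + seq_len(nsat)] <- pmax(sat, 0)
    }
    R <- peak_render_matrix(mzs, cfg$scheme, cfg$peak_sigma)
    newrows <- as.matrix(Hm %*% R)
    if (cfg$noise_sigma > 0) {
      newrows <- newrows + abs(stats::rnorm(length(newrows), 0, cfg$noise_sigma))
    }
    dataset$intensities[mod, ] <- newrows
  })
  attr(dataset, "noise_pixels") <- mod
  dataset
}
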