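#' Equidistant m/z binning scheme
#'
#' Defines the shared mass axis used by every pipeline stage: `n_bins`
#' half-open intervals `[lo_mz + i*bin_width, lo_mz + (i+1)*bin_width)` for
#' `i = 0, ..., n_bins - 1`. Bin centers sit at `lo_mz + (i + 0.5)*bin_width`.
#'
#' @param lo_mz Lower end of the mass range (Da), inclusive.
#' @param hi_mz Upper end of the mass range (Da), exclusive.
#' @param bin_width Bin width (Da).
#' @return An object of class `binning_scheme` with elements `lo_mz`,
#'   `hi_mz`, `bin_width` and `n_bins`.
#' @examples
#' sc <- binning_scheme(590, 800, 0.01)
#' sc$n_bins
#' @export
binning_scheme <- function(lo_mz, hi_mz, bin_width) {
  stopifnot(is.numeric(lo_mz), is.numeric(hi_mz), is.numeric(bin_width))
  if (!(lo_mz < hi_mz)) stop("binning_scheme: lo_mz must be < hi_mz")
  if (!(bin_width > 0)) stop("binning_scheme: bin_width must be > 0")
  n_bins <- floor((hi_mz - lo_mz) / bin_width + 1e-9)
  if (n_bins < 1) stop("binning_scheme: range shorter than one bin")
  structure(
    list(lo_mz = lo_mz, hi_mz = hi_mz, bin_width = bin_width,
         n_bins = as.integer(n_bins)),
    class = "binning_scheme"
  )
}

#' Bin centers of a binning scheme
#' @param scheme A [binning_scheme()].
#' @return Numeric vector of length `scheme$n_bins` (Da).
#' @export
bin_centers <- function(scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  scheme$lo_mz + (seq_len(scheme$n_bins) - 0.5) * scheme$bin_width
}

#' Map m/z values to bin indices
#'
#' Uses the half-open, lower-inclusive convention: a value exactly at
#' `lo_mz` falls in bin 1; a value at or beyond `hi_mz` (or the end of the
#' last full bin) maps to `NA`.
#'
#' @param scheme A [binning_scheme()].
#' @param mz Numeric vector of m/z values (Da).
#' @return Integer vector of 1-based bin indices, `NA` for out-of-range.
#' @export
mz_to_bin <- function(scheme, mz) {
  stopifnot(inherits(scheme, "binning_scheme"))
  idx <- floor((mz - scheme$lo_mz) / scheme$bin_width) + 1
  idx[idx < 1 | idx > scheme$n_bins | !is.finite(mz)] <- NA
  as.integer(idx)
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("<binning_scheme> %.4f-%.4f Da, width %g Da, %d bins\n",
              x$lo_mz, x$hi_mz, x$bin_width, x$n_bins))
  invisible(x)
}

#' @export
format.binning_scheme <- function(x, ...) {
  sprintf("[%g, %g) Da @ %g Da", x$lo_mz, x$hi_mz, x$bin_width)
}
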