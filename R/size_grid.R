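#' Size grids for particle sizing instruments
#'
#' A `size_grid` holds the diameter bin edges (nm) of a size-resolved particle
#' counter, with geometric bin midpoints. Two instrument presets are provided:
#' an SMPS-style mobility grid covering 7--300 nm and an OPS-style optical grid
#' covering 300--10000 nm; stitching the two yields a composite grid spanning
#' the full 7 nm -- 10 um range.
#'
#' @param bin_edges Numeric vector of strictly increasing bin-edge diameters in
#'   nm, length `n + 1` for `n` bins. All edges must be positive.
#' @param instrument_label One of `"smps"`, `"ops"`, `"composite"`.
#' @return An object of class `size_grid`: a list with `bin_edges`, `bin_mids`
#'   (geometric midpoints, `sqrt(lo * hi)`) and `instrument_label`.
#' @examples
#' g <- smps_grid()
#' range(g$bin_edges) # 7 300
#' @export
size_grid <- function(bin_edges, instrument_label = c("composite", "smps", "ops")) {
  instrument_label <- match.arg(instrument_label)
  bin_edges <- as.numeric(bin_edges)
  if (length(bin_edges) < 2L) {
    stop("`bin_edges` must contain at least two edges", call. = FALSE)
  }
  if (any(!is.finite(bin_edges)) || any(bin_edges <= 0)) {
    stop("`bin_edges` must be finite and positive", call. = FALSE)
  }
  if (any(diff(bin_edges) <= 0)) {
    stop("`bin_edges` must be strictly increasing", call. = FALSE)
  }
  n <- length(bin_edges) - 1L
  mids <- sqrt(bin_edges[-(n + 1L)] * bin_edges[-1L])
  structure(
    list(bin_edges = bin_edges, bin_mids = mids,
         instrument_label = instrument_label),
    class = "size_grid"
  )
}

#' @rdname size_grid
#' @param n_bins Number of logarithmically spaced bins.
#' @export
smps_grid <- function(n_bins = 32L) {
  size_grid(exp(seq(log(7), log(300), length.out = n_bins + 1L)), "smps")
}

#' @rdname size_grid
#' @export
ops_grid <- function(n_bins = 16L) {
  size_grid(exp(seq(log(300), log(10000), length.out = n_bins + 1L)), "ops")
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf("<size_grid: %s, %d bins, %.3g-%.3g nm>\n",
              x$instrument_label, length(x$bin_mids),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' @export
length.size_grid <- function(x) length(x$bin_mids)

# decadal log10 widths of each bin, used by dN/dlogDp normalization
dlog10 <- function(grid) {
  diff(log10(grid$bin_edges))
}
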