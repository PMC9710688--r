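#' Build a center-aligned bin grid
#'
#' All regions of a set share one grid: an odd number `n_bins` of `bin_size`-bp
#' bins whose centers sit at signed offsets from the region center, the middle
#' bin centered on the region center itself.  This makes bin `j` positionally
#' comparable across regions of unequal length, which is what allows profiles
#' to be averaged over a region set.
#'
#' @param bin_size bin width in bp (even, >= 50).
#' @param n_bins odd number of bins (>= 5).  The default 41 x 500 bp grid
#'   spans roughly +/-10 kb around each region center.
#' @return A `bin_grid`: list with `bin_size`, `n_bins`, `half_span`
#'   (= ((n_bins-1)/2 + 0.5) * bin_size) and `offsets` (bin-center offsets, bp).
#' @examples
#' build_bin_grid(500, 5)$offsets  # -1000 -500 0 500 1000
#' @export
build_bin_grid <- function(bin_size = 500, n_bins = 41) {
  if (n_bins %% 2 == 0) stopf("n_bins must be odd, got %d", n_bins)
  if (n_bins < 5) stopf("n_bins must be >= 5")
  if (bin_size < 50) stopf("bin_size must be >= 50 bp")
  if (bin_size %% 2 != 0) stopf("bin_size must be even so bin edges are integral")
  m <- (n_bins - 1) / 2
  structure(list(bin_size = as.integer(bin_size), n_bins = as.integer(n_bins),
                 half_span = (m + 0.5) * bin_size,
                 offsets = seq(-m, m) * bin_size),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d bins x %d bp, half-span %g bp (+/-%g kb)\n",
              x$n_bins, x$bin_size, x$half_span, x$half_span / 1000))
  invisible(x)
}

#' Genomic bin windows for one region
#'
#' The region is reduced to its center `c = floor((start + end)/2)` and
#' re-expanded to `n_bins` contiguous windows of `bin_size` bp tiling
#' `[c - half_span, c + half_span)`.
#'
#' @param chrom,start,end region in 0-based half-open coordinates.
#' @param grid a [build_bin_grid()] grid.
#' @param chrom_len optional chromosome length; when given and the window
#'   exceeds `[0, chrom_len)` the region is flagged for dropping.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open,
#'   one row per bin) and attribute `drop` (logical).
#' @export
region_windows <- function(chrom, start, end, grid, chrom_len = NULL) {
  ctr <- floor((start + end) / 2)
  w <- grid$bin_size
  bs <- ctr + grid$offsets - w / 2
  be <- bs + w
  drop <- bs[1] < 0
  if (!is.null(chrom_len)) drop <- drop || be[length(be)] > chrom_len
  structure(data.frame(chrom = chrom, start = bs, end = be), drop = drop)
}

## Region centers (0-based) for a GRanges.
region_centers <- function(gr) {
  floor(((GenomicRanges::start(gr) - 1) + GenomicRanges::end(gr)) / 2)
}
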