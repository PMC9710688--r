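#' Estimate the genome-background normalization factor
#'
#' Mean per-base fragment coverage over `n_windows` randomly placed windows
#' (seeded, uniform over the genome, avoiding chromosome edges).  Dividing
#' binned coverage by this factor puts samples of different sequencing depth
#' on a common scale where 1.0 is the genome-wide average, without normalizing
#' away a genuine dip at the region set itself.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param n_windows number of random windows (>= 100).
#' @param window_len window length in bp.
#' @param seed integer seed for window placement.
#' @param min_mapq,fragment_len_range fragment filters, as in
#'   [extract_fragments()].
#' @return Mean fragments-per-bp coverage (scalar, > 0).
#' @export
estimate_normalization_factor <- function(bam_path, n_windows = 200,
                                          window_len = 1000, seed = 1,
                                          min_mapq = 20,
                                          fragment_len_range = c(70, 400)) {
  if (n_windows < 100) stopf("n_windows must be >= 100")
  check_bam_index(bam_path)
  sl <- bam_seqlengths(bam_path)
  margin <- ceiling(fragment_len_range[2])
  usable <- pmax(0, sl - window_len - 2 * margin)
  if (all(usable <= 0)) stopf("genome too small for %d-bp sampling windows", window_len)
  if (sum(usable) < n_windows * window_len)
    warnf("genome smaller than n_windows disjoint windows; sampling with replacement")
  wins <- with_seed(seed, {
    chr_idx <- sample.int(length(sl), n_windows, replace = TRUE,
                          prob = usable / sum(usable))
    st <- margin + floor(runif(n_windows) * usable[chr_idx])
    GenomicRanges::GRanges(names(sl)[chr_idx],
                           IRanges::IRanges(st + 1, st + window_len))
  })
  frs <- fragments_for_windows(bam_path, wins, min_mapq, fragment_len_range)
  if (sum(vapply(frs, nrow, 0L)) == 0) stopf("no fragments found in BAM %s", bam_path)
  cov <- vapply(seq_along(frs), function(i) {
    ws <- GenomicRanges::start(wins)[i] - 1
    we <- GenomicRanges::end(wins)[i]
    fr <- frs[[i]]
    sum(pmin(fr$end, we) - pmax(fr$start, ws)) / window_len
  }, 0)
  mean(cov)
}

#' Compute the binned, normalized coverage matrix for a region set
#'
#' Entry (i, j) is the mean fragment depth over the positions of bin j of
#' region i (sum of per-fragment overlaps divided by bin size), divided by
#' `normalization_factor`.  Regions whose bin window would run past a
#' chromosome end are dropped (recorded in `dropped`), not padded.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param region_set a `region_set` from [read_region_sets()].
#' @param grid a [build_bin_grid()] grid.
#' @param normalization_factor fragments-per-bp background coverage (> 0).
#' @param sample_id label stored with the matrix.
#' @param min_mapq,fragment_len_range fragment filters.
#' @param midpoint logical; count fragment midpoints per bin (divided by bin
#'   size) instead of mean fragment depth.  Default `FALSE`.
#' @return A `coverage_matrix`: list with `values` (n_regions x n_bins),
#'   `regions` (retained `GRanges`), `dropped` (indices), `grid`,
#'   `normalization_factor`, `set_name`, `sample_id`, `corrected` flag.
#' @export
compute_coverage_matrix <- function(bam_path, region_set, grid,
                                    normalization_factor, sample_id = "sample",
                                    min_mapq = 20, fragment_len_range = c(70, 400),
                                    midpoint = FALSE) {
  stopifnot(inherits(region_set, "region_set"), inherits(grid, "bin_grid"))
  if (!is.numeric(normalization_factor) || normalization_factor <= 0)
    stopf("normalization_factor must be > 0")
  check_bam_index(bam_path)
  sl <- bam_seqlengths(bam_path)
  gr <- region_set$regions
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  missing_chr <- setdiff(unique(chroms), names(sl))
  if (length(missing_chr))
    stopf("region chromosome(s) not in BAM header: %s",
          paste(missing_chr, collapse = ", "))
  ctr <- region_centers(gr)
  win_s <- ctr - grid$half_span         # 0-based window start
  win_e <- ctr + grid$half_span
  drop <- win_s < 0 | win_e > sl[chroms]
  if (any(drop))
    warnf("dropping %d region(s) whose windows exceed chromosome bounds", sum(drop))
  if (all(drop)) stopf("all regions dropped: windows exceed chromosome bounds")
  keep <- which(!drop)
  wins <- GenomicRanges::GRanges(chroms[keep],
                                 IRanges::IRanges(win_s[keep] + 1, win_e[keep]))
  frs <- fragments_for_windows(bam_path, wins, min_mapq, fragment_len_range)
  w <- grid$bin_size
  k <- grid$n_bins
  vals <- matrix(0, nrow = length(keep), ncol = k)
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    bs <- ctr[i] + grid$offsets - w / 2
    fr <- frs[[ii]]
    if (nrow(fr) == 0) next
    if (midpoint) {
      mid <- floor((fr$start + fr$end) / 2)
      idx <- floor((mid - bs[1]) / w) + 1
      idx <- idx[idx >= 1 & idx <= k]
      vals[ii, ] <- tabulate(idx, k) / w
    } else {
      ## overlap of every fragment with every bin, in bp
      ov <- outer(fr$end, bs + w, FUN = pmin) - outer(fr$start, bs, FUN = pmax)
      ov[ov < 0] <- 0
      vals[ii, ] <- colSums(ov) / w
    }
  }
  vals <- vals / normalization_factor
  structure(list(values = vals, regions = gr[keep],
                 dropped = unname(which(drop)),
                 grid = grid, normalization_factor = normalization_factor,
                 set_name = region_set$set_name, sample_id = sample_id,
                 corrected = FALSE),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix> %s / %s: %d regions x %d bins (%s), factor %.4g%s\n",
              x$sample_id, x$set_name, nrow(x$values), ncol(x$values),
              if (x$corrected) "bias-corrected" else "raw", x$normalization_factor,
              if (length(x$dropped)) sprintf(", %d dropped", length(x$dropped)) else ""))
  invisible(x)
}

#' Export a coverage matrix as (gzipped) TSV
#'
#' Rows are regions (id column first), columns the bin-center offsets in bp.
#'
#' @param cm a `coverage_matrix`.
#' @param path output path; gzipped when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
export_coverage_matrix <- function(cm, path) {
  df <- as.data.frame(cm$values)
  names(df) <- as.character(cm$grid$offsets)
  id <- if (!is.null(cm$regions$name)) cm$regions$name
        else sprintf("region_%d", seq_len(nrow(df)))
  df <- cbind(region_id = id, df)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
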