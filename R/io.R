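## Readers for the four standard inputs: FASTA, bigWig, BAM (fragments), BED
## (see regions.R).  All window arguments are 0-based half-open, matching BED.

#' Read reference sequence for a window
#'
#' @param fasta_path indexed (or indexable) FASTA file.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window.
#' @return Uppercase DNA string over {A,C,G,T,N}; windows extending past the
#'   chromosome end are clipped (attribute `clipped` carries the number of
#'   bases lost; a fully out-of-range window yields an empty string).
#' @export
read_sequence <- function(fasta_path, chrom, start, end) {
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  sl <- Rsamtools::scanFaIndex(fa)
  len <- GenomicRanges::width(sl)[match(chrom, as.character(GenomeInfoDb::seqnames(sl)))]
  if (is.na(len)) stopf("chromosome '%s' not present in FASTA %s", chrom, fasta_path)
  s <- max(0, start); e <- min(end, len)
  clipped <- (end - start) - max(0, e - s)
  if (e <= s) return(structure("", clipped = end - start))
  seq <- Rsamtools::scanFa(fa, GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, e)))
  structure(toupper(as.character(seq[[1]])), clipped = clipped)
}

#' Read per-base mappability for a window
#'
#' Positions not covered by any bigWig interval are filled with 0.
#'
#' @inheritParams read_sequence
#' @param bigwig_path bigWig track with values in [0, 1].
#' @return Numeric vector of length `end - start`.
#' @export
read_mappability <- function(bigwig_path, chrom, start, end) {
  bwf <- rtracklayer::BigWigFile(bigwig_path)
  sl <- GenomeInfoDb::seqlengths(bwf)
  if (!chrom %in% names(sl)) stopf("chromosome '%s' not present in bigWig %s",
                                   chrom, bigwig_path)
  n <- end - start
  stopifnot(n >= 0)
  out <- numeric(n)
  qs <- max(0, start); qe <- min(end, sl[[chrom]])
  if (qe <= qs) return(out)
  hits <- rtracklayer::import.bw(bwf, which = GenomicRanges::GRanges(
    chrom, IRanges::IRanges(qs + 1, qe)))
  if (length(hits)) {
    for (i in seq_along(hits)) {
      a <- max(GenomicRanges::start(hits)[i] - 1, start) - start + 1
      b <- min(GenomicRanges::end(hits)[i], end) - start
      if (b >= a) out[a:b] <- hits$score[i]
    }
  }
  out
}

## Sequence lengths from a BAM header, as a named integer vector.
bam_seqlengths <- function(bam_path) {
  hdr <- Rsamtools::scanBamHeader(bam_path)[[1]]$targets
  if (is.null(hdr) || !length(hdr)) stopf("BAM %s has no @SQ header lines", bam_path)
  hdr
}

check_bam_index <- function(bam_path) {
  bai <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  if (!any(file.exists(bai)))
    stopf("BAM index not found for %s; index it first (e.g. samtools index)", bam_path)
}

#' Extract DNA fragments from a paired-end BAM
#'
#' Each properly paired template yields one fragment, reconstructed from the
#' leftmost mate's position and the template length (TLEN) and counted exactly
#' once, from the mate with positive TLEN.  Duplicates, secondary and
#' supplementary alignments are excluded; the representative mate must have
#' MAPQ >= `min_mapq`; fragment length must fall inside `fragment_len_range`.
#' Fragments overlapping the window by at least 1 bp are returned.
#'
#' @param bam_path coordinate-sorted, indexed BAM.
#' @param chrom,start,end 0-based half-open query window.
#' @param min_mapq minimum mapping quality of the representative mate.
#' @param fragment_len_range numeric length-2, inclusive bounds on fragment
#'   length in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `length`
#'   (0-based half-open), ordered by start.
#' @export
extract_fragments <- function(bam_path, chrom, start, end,
                              min_mapq = 20, fragment_len_range = c(70, 400)) {
  check_bam_index(bam_path)
  sl <- bam_seqlengths(bam_path)
  if (!chrom %in% names(sl)) stopf("chromosome '%s' not in BAM header", chrom)
  li <- fragments_for_windows(bam_path,
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, max(start + 1, end))),
    min_mapq, fragment_len_range)
  fr <- li[[1]]
  fr[order(fr$start, fr$end), , drop = FALSE]
}

## Fetch fragments overlapping each query range (GRanges, 1-based) in one
## scanBam pass.  Queries are padded by the max fragment length so fragments
## whose representative mate starts left of the window are not missed, then
## filtered back to true overlap.  Returns a list of data.frames, one per
## query range.
fragments_for_windows <- function(bam_path, which, min_mapq, fragment_len_range) {
  sl <- bam_seqlengths(bam_path)
  pad <- ceiling(fragment_len_range[2])
  padded <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(which),
    IRanges::IRanges(pmax(1, GenomicRanges::start(which) - pad),
                     GenomicRanges::end(which)))
  flags <- Rsamtools::scanBamFlag(isProperPair = TRUE, isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, what = c("pos", "isize", "mapq"),
                                   which = padded)
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam_path), param = param)
  ## scanBam groups query ranges by chromosome; map results back to the
  ## caller's window order (order() is stable, preserving within-chrom order)
  ord <- order(match(as.character(GenomeInfoDb::seqnames(padded)),
                     GenomeInfoDb::seqlevels(padded)))
  out <- vector("list", length(which))
  for (j in seq_along(res)) {
    i <- ord[j]
    r <- res[[j]]
    mq <- r$mapq
    mq[is.na(mq)] <- 0L  # missing MAPQ treated as 0
    keep <- !is.na(r$isize) & r$isize > 0 & !is.na(r$pos) & mq >= min_mapq
    s0 <- r$pos[keep] - 1L
    e0 <- s0 + r$isize[keep]
    len <- e0 - s0
    ok <- len >= fragment_len_range[1] & len <= fragment_len_range[2]
    s0 <- s0[ok]; e0 <- e0[ok]
    ws <- GenomicRanges::start(which)[i] - 1L
    we <- GenomicRanges::end(which)[i]
    ov <- e0 > ws & s0 < we
    out[[i]] <- data.frame(
      chrom = rep(as.character(GenomeInfoDb::seqnames(which))[i], sum(ov)),
      start = s0[ov], end = e0[ov], length = (e0 - s0)[ov])
  }
  out
}
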