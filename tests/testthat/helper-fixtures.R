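## Fixture builders shared across test files.  Everything is generated in
## code at test time; simulated bundles are cached per R session so several
## test files can reuse one simulation.

fixture_root <- local({
  d <- file.path(tempdir(), "cfdip-fixtures")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
})

.fixture_cache <- new.env(parent = emptyenv())

## Simulate (or fetch the cached) bundle for a given config.
cached_bundle <- function(name, cfg) {
  if (!is.null(.fixture_cache[[name]])) return(.fixture_cache[[name]])
  out <- simulate_bundle(cfg, file.path(fixture_root, name))
  .fixture_cache[[name]] <- out
  out
}

## Write a BAM containing exactly the given fragments (0-based half-open),
## as proper pairs with the given read length.  Returns the BAM path.
make_test_bam <- function(fragments, chrom_lengths, dir = tempfile("bam"),
                          read_len = 30, mapq = 60, extra_sam_lines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- character(0)
  if (nrow(fragments) > 0) {
    s0 <- as.integer(fragments$start); e0 <- as.integer(fragments$end)
    rl <- as.integer(read_len)
    stopifnot(all(e0 - s0 >= rl))
    seqq <- vapply(e0 - s0, function(l) paste(rep("A", rl), collapse = ""), "")
    qual <- paste(rep("I", rl), collapse = "")
    qn <- sprintf("t%05d", seq_len(nrow(fragments)))
    body <- as.vector(rbind(
      paste(qn, 99L, fragments$chrom, s0 + 1L, mapq, paste0(rl, "M"), "=",
            e0 - rl + 1L, e0 - s0, seqq, qual, sep = "\t"),
      paste(qn, 147L, fragments$chrom, e0 - rl + 1L, mapq, paste0(rl, "M"),
            "=", s0 + 1L, -(e0 - s0), seqq, qual, sep = "\t")))
  }
  sam <- file.path(dir, "t.sam")
  writeLines(c(hdr, body, extra_sam_lines), sam)
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                   indexDestination = TRUE)
}

## Write a small FASTA (named character vector of sequences) and index it.
make_test_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  Rsamtools::indexFa(path)
  path
}

## Write a bigWig from a data.frame(chrom, start, end, value) over the given
## chromosome lengths (0-based half-open intervals).
make_test_bigwig <- function(intervals, chrom_lengths,
                             path = tempfile(fileext = ".bw")) {
  gr <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start + 1,
                                                intervals$end),
                               score = intervals$value)
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths
  rtracklayer::export.bw(gr, path)
  path
}

## Brute-force per-base coverage oracle: mean fragment depth per bin,
## counting overlapping fragments position by position.
oracle_bin_coverage <- function(fragments, bin_starts, bin_size) {
  vapply(bin_starts, function(bs) {
    depth <- vapply(bs:(bs + bin_size - 1), function(p)
      sum(fragments$start <= p & fragments$end > p), 0)
    mean(depth)
  }, 0)
}

## Aggregated profile object from raw vectors (for direct dip-fit tests).
profile_signature <- function(offsets, values, grid,
                              set_name = "test", sample_id = "t") {
  structure(list(set_name = set_name, sample_id = sample_id,
                 bin_offsets = offsets, mean_profile = values,
                 se_profile = rep(0, length(values)),
                 n_regions_used = 1L, grid = grid),
            class = "agg_signature")
}

## One small standard bundle many tests share: 60 regions, 4x, dip 0.3.
std_bundle <- function() {
  cached_bundle("std", sim_config(n_regions = 60, mean_coverage = 4,
                                  dip_depth = 0.3, dip_sigma = 1500,
                                  seed = 421))
}
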