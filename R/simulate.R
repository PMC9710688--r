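#' Configuration for a synthetic cfDNA input bundle
#'
#' Defines the study conditions the simulator emulates: a small multi-
#' chromosome genome, a set of open-chromatin-like regions, a cfDNA fragment
#' population with a Gaussian coverage dip centered on each region, optional
#' GC-dependent sampling bias, and a mappability track.  Defaults mirror a
#' typical cfDNA region-set analysis: hundreds of ~1 kb regions, 5x depth,
#' fragment lengths ~N(167, 20) bp truncated to [70, 400] (mononucleosomal
#' cfDNA), human-like 41% GC.
#'
#' Fragment midpoints are sampled with per-position rate
#' `r(x) = base_rate * (1 - dip_depth * exp(-D^2 / (2 * dip_sigma^2)))`,
#' `D` the distance to the nearest region center, then thinned with
#' probability proportional to `exp(gc_bias * (GC_frag - 0.5))`.
#'
#' @param n_regions number of regions (>= 1).
#' @param region_len region length in bp.
#' @param dip_depth fractional coverage reduction at region centers, in [0, 1).
#' @param dip_sigma Gaussian dip scale in bp (> 0).
#' @param gc_bias slope of log sampling weight vs fragment GC fraction
#'   (0 = unbiased).
#' @param mean_coverage target haploid depth (x).
#' @param fragment_len_mean,fragment_len_sd,fragment_len_range fragment length
#'   distribution: normal, truncated to the range.
#' @param read_len read length for the emitted pairs (<= min fragment length).
#' @param gc_content genome GC composition.
#' @param n_chroms number of chromosomes the regions are spread over.
#' @param region_spacing center-to-center slot spacing in bp; must exceed the
#'   analysis window (default 41 x 500 bp grid) so windows never overlap.
#' @param edge_margin bp kept region-free at chromosome ends.
#' @param low_mappability optional data.frame (`chrom`, `start`, `end`,
#'   `value`) of intervals where the mappability track drops below 1.
#' @param set_name name of the region set / BED file.
#' @param seed integer seed; all simulator randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 500, region_len = 1000,
                       dip_depth = 0.3, dip_sigma = 1500,
                       gc_bias = 0, mean_coverage = 5,
                       fragment_len_mean = 167, fragment_len_sd = 20,
                       fragment_len_range = c(70, 400), read_len = 50,
                       gc_content = 0.41, n_chroms = 2,
                       region_spacing = 22500, edge_margin = 5000,
                       low_mappability = NULL, set_name = "regions",
                       seed = 1) {
  stopifnot(dip_depth >= 0, dip_depth < 1, dip_sigma > 0, mean_coverage > 0,
            n_regions >= 1, read_len <= fragment_len_range[1],
            gc_content > 0, gc_content < 1, n_chroms >= 1)
  cfg <- list(n_regions = n_regions, region_len = region_len,
              dip_depth = dip_depth, dip_sigma = dip_sigma, gc_bias = gc_bias,
              mean_coverage = mean_coverage,
              fragment_len_mean = fragment_len_mean,
              fragment_len_sd = fragment_len_sd,
              fragment_len_range = fragment_len_range, read_len = read_len,
              gc_content = gc_content, n_chroms = n_chroms,
              region_spacing = region_spacing, edge_margin = edge_margin,
              low_mappability = low_mappability, set_name = set_name,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' Generate a complete synthetic input bundle
#'
#' Writes, under `out_dir`: an indexed FASTA toy genome, a BED region set, a
#' coordinate-sorted and indexed paired-end BAM whose templates reproduce each
#' simulated fragment exactly, a bigWig mappability track (1.0 everywhere
#' except configured intervals), and a truth JSON recording every parameter
#' plus the emitted fragment count.  Identical config + seed give identical
#' outputs.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return List with elements `fasta`, `bed`, `bam`, `bigwig`, `truth_json`
#'   (paths) and `truth` (the truth record).
#' @export
simulate_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  with_seed(config$seed, simulate_bundle_impl(config, out_dir))
}

simulate_bundle_impl <- function(cfg, out_dir) {
  geom <- sim_geometry(cfg)
  window_span <- 2 * build_bin_grid()$half_span
  if (sum(geom$chrom_len) < 10 * window_span)
    stopf("genome (%d bp) shorter than 10 analysis windows", sum(geom$chrom_len))

  ## --- genome ---
  p <- c(A = (1 - cfg$gc_content) / 2, C = cfg$gc_content / 2,
         G = cfg$gc_content / 2, T = (1 - cfg$gc_content) / 2)
  chrom_seq <- lapply(geom$chrom_len, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""))
  names(chrom_seq) <- geom$chrom
  fasta <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(chrom_seq)), fasta)
  Rsamtools::indexFa(fasta)

  ## --- regions (non-overlapping analysis windows by construction) ---
  jit_max <- max(0, floor((cfg$region_spacing - window_span) / 2) - 1)
  jitter <- runif_int(cfg$n_regions, -min(jit_max, 1000), min(jit_max, 1000))
  centers <- geom$slot_center + jitter
  reg_s <- centers - floor(cfg$region_len / 2)
  reg_e <- reg_s + cfg$region_len
  bed <- file.path(out_dir, paste0(cfg$set_name, ".bed"))
  write.table(data.frame(geom$region_chrom, reg_s, reg_e,
                         sprintf("%s_%d", cfg$set_name, seq_len(cfg$n_regions))),
              bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  ## --- fragments: accept/reject against dip and GC thinning ---
  cum_gc <- lapply(chrom_seq, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    c(0, cumsum(v == "G" | v == "C"))
  })
  centers_by_chrom <- split(centers, geom$region_chrom)
  target_bases <- cfg$mean_coverage * sum(geom$chrom_len)
  frag <- sample_fragments(cfg, geom, cum_gc, centers_by_chrom, target_bases)

  ## --- reads as proper pairs reproducing each fragment exactly ---
  bam <- write_pairs_bam(frag, chrom_seq, geom, cfg$read_len,
                         file.path(out_dir, "sample"))

  ## --- mappability ---
  bigwig <- file.path(out_dir, "mappability.bw")
  write_mappability_bw(bigwig, geom, cfg$low_mappability)

  ## --- truth record ---
  truth <- list(dip_depth_true = cfg$dip_depth, dip_sigma_true = cfg$dip_sigma,
                gc_bias_strength = cfg$gc_bias, mean_coverage = cfg$mean_coverage,
                seed = cfg$seed, n_regions = cfg$n_regions,
                region_len = cfg$region_len, set_name = cfg$set_name,
                chroms = geom$chrom, chrom_lengths = geom$chrom_len,
                n_fragments = nrow(frag),
                fragment_len_mean = cfg$fragment_len_mean,
                fragment_len_sd = cfg$fragment_len_sd,
                fragment_len_range = cfg$fragment_len_range,
                read_len = cfg$read_len, gc_content = cfg$gc_content)
  truth_json <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(fasta = fasta, bed = bed, bam = bam, bigwig = bigwig,
       truth_json = truth_json, truth = truth)
}

## Chromosome geometry: regions are assigned to chromosomes round-robin and
## sit in non-overlapping slots of region_spacing bp, edge_margin clear of
## both chromosome ends.
sim_geometry <- function(cfg) {
  chrom <- sprintf("chrS%d", seq_len(cfg$n_chroms))
  n_per <- diff(floor(seq(0, cfg$n_regions, length.out = cfg$n_chroms + 1)))
  n_per[cfg$n_chroms] <- cfg$n_regions - sum(n_per[-cfg$n_chroms])
  chrom_len <- n_per * cfg$region_spacing + 2 * cfg$edge_margin
  slot_idx <- unlist(lapply(n_per, seq_len))
  region_chrom <- rep(chrom, n_per)
  slot_center <- cfg$edge_margin + (slot_idx - 0.5) * cfg$region_spacing
  list(chrom = chrom, chrom_len = chrom_len, n_per = n_per,
       region_chrom = region_chrom, slot_center = floor(slot_center))
}

## Draw fragments in blocks until the target number of sequenced bases is
## reached.  Returns data.frame(chrom, start, end) in 0-based half-open coords.
sample_fragments <- function(cfg, geom, cum_gc, centers_by_chrom, target_bases) {
  gmax <- exp(abs(cfg$gc_bias) * 0.5)
  acc <- list(); got <- 0
  block <- max(20000L, ceiling(target_bases / cfg$fragment_len_mean / 10))
  guard <- 0L
  while (got < target_bases) {
    guard <- guard + 1L
    if (guard > 2000L) stopf("fragment sampling failed to reach target depth")
    ci <- sample.int(length(geom$chrom), block, replace = TRUE,
                     prob = geom$chrom_len / sum(geom$chrom_len))
    len <- round(rnorm(block, cfg$fragment_len_mean, cfg$fragment_len_sd))
    bad <- len < cfg$fragment_len_range[1] | len > cfg$fragment_len_range[2]
    while (any(bad)) {  # truncated normal by resampling
      len[bad] <- round(rnorm(sum(bad), cfg$fragment_len_mean, cfg$fragment_len_sd))
      bad <- len < cfg$fragment_len_range[1] | len > cfg$fragment_len_range[2]
    }
    maxs <- geom$chrom_len[ci] - len
    ok <- maxs >= 0
    ci <- ci[ok]; len <- len[ok]; maxs <- maxs[ok]
    st <- floor(runif(length(ci)) * (maxs + 1))
    mid <- st + len / 2
    ## dip acceptance: distance to nearest region center on the same chromosome
    p_dip <- rep(1, length(ci))
    for (k in seq_along(geom$chrom)) {
      sel <- ci == k
      if (!any(sel)) next
      ctrs <- centers_by_chrom[[geom$chrom[k]]]
      if (is.null(ctrs) || !length(ctrs)) next
      ctrs <- sort(ctrs)
      j <- findInterval(mid[sel], ctrs)
      lo <- pmax(j, 1); hi <- pmin(j + 1, length(ctrs))
      d <- pmin(abs(mid[sel] - ctrs[lo]), abs(mid[sel] - ctrs[hi]))
      p_dip[sel] <- 1 - cfg$dip_depth * exp(-d^2 / (2 * cfg$dip_sigma^2))
    }
    ## GC thinning, normalized so the acceptance probability is <= 1
    p_gc <- rep(1, length(ci))
    if (cfg$gc_bias != 0) {
      gc <- mapply(function(k, s, l) (cum_gc[[k]][s + l + 1] - cum_gc[[k]][s + 1]) / l,
                   ci, st, len)
      p_gc <- exp(cfg$gc_bias * (gc - 0.5)) / gmax
    }
    u <- runif(length(ci))
    keep <- u < p_dip * p_gc
    if (any(keep)) {
      df <- data.frame(chrom = geom$chrom[ci[keep]], start = st[keep],
                       end = st[keep] + len[keep])
      acc[[length(acc) + 1]] <- df
      got <- got + sum(len[keep])
    }
  }
  out <- do.call(rbind, acc)
  ## trim the last block's overshoot so total bases land on the target
  m <- which(cumsum(out$end - out$start) >= target_bases)[1]
  if (!is.na(m)) out <- out[seq_len(m), , drop = FALSE]
  out
}

## Emit each fragment as a proper read pair (perfect reference match, dummy
## qualities), convert to a coordinate-sorted indexed BAM via Rsamtools.
write_pairs_bam <- function(frag, chrom_seq, geom, read_len, dest_prefix) {
  n <- nrow(frag)
  if (n == 0) stopf("simulator produced no fragments")
  ## keep coordinates integer end to end, or paste() may emit scientific
  ## notation ("1e+05") in the SAM text
  s0 <- as.integer(frag$start)
  e0 <- as.integer(frag$end)
  rl <- as.integer(read_len)
  qual <- paste(rep("I", rl), collapse = "")
  txt <- unlist(chrom_seq[frag$chrom], use.names = FALSE)
  seq1 <- substring(txt, s0 + 1L, s0 + rl)
  seq2 <- substring(txt, e0 - rl + 1L, e0)
  qname <- sprintf("frag%08d", seq_len(n))
  cigar <- paste0(rl, "M")
  tlen <- e0 - s0
  r1 <- paste(qname, 99L, frag$chrom, s0 + 1L, 60L, cigar, "=",
              e0 - rl + 1L, tlen, seq1, qual, sep = "\t")
  r2 <- paste(qname, 147L, frag$chrom, e0 - rl + 1L, 60L, cigar, "=",
              s0 + 1L, -tlen, seq2, qual, sep = "\t")
  sam <- file.path(dirname(dest_prefix), paste0(basename(dest_prefix), ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", geom$chrom, geom$chrom_len))
  writeLines(c(hdr, rbind(r1, r2)), sam)
  bam <- Rsamtools::asBam(sam, dest_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

write_mappability_bw <- function(path, geom, low) {
  grs <- list()
  for (k in seq_along(geom$chrom)) {
    ch <- geom$chrom[k]; L <- geom$chrom_len[k]
    if (!is.null(low) && any(low$chrom == ch)) {
      lo <- low[low$chrom == ch, , drop = FALSE]
      lo <- lo[order(lo$start), , drop = FALSE]
      bnd <- sort(unique(c(0, lo$start, lo$end, L)))
      st <- utils::head(bnd, -1); en <- bnd[-1]
      val <- rep(1, length(st))
      for (j in seq_len(nrow(lo)))
        val[st >= lo$start[j] & en <= lo$end[j]] <- lo$value[j]
    } else {
      st <- 0; en <- L; val <- 1
    }
    ## the UCSC writer mishandles tracks where every chromosome is a single
    ## run; split singleton runs into two unequal pieces of the same value
    if (length(st) == 1 && en - st > 2) {
      cut <- st + floor((en - st) / 3)
      st <- c(st, cut); en <- c(cut, en); val <- c(val, val)
    }
    grs[[k]] <- GenomicRanges::GRanges(ch, IRanges::IRanges(st + 1, en), score = val)
  }
  gr <- suppressWarnings(do.call(c, grs))
  GenomeInfoDb::seqlengths(gr) <- setNames(geom$chrom_len, geom$chrom)
  rtracklayer::export.bw(gr, path)
  path
}
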