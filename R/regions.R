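#' Read BED files into region sets
#'
#' Each BED3+ file (optionally gzipped) becomes one region set named after the
#' file basename (without `.bed`/`.bed.gz`).  BED coordinates are 0-based
#' half-open and are preserved unchanged; internally regions are carried as a
#' [GenomicRanges::GRanges] (1-based closed), converted back and forth at the
#' boundaries.
#'
#' @param bed_paths character vector of BED file paths.
#' @param set_names optional character vector overriding the derived names.
#' @return A list of `region_set` objects, each a list with elements
#'   `set_name`, `regions` (a `GRanges`), and `source_path`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300\tr1", bed)
#' rs <- read_region_sets(bed)[[1]]
#' GenomicRanges::width(rs$regions)  # 200
#' @export
read_region_sets <- function(bed_paths, set_names = NULL) {
  stopifnot(length(bed_paths) >= 1)
  if (!is.null(set_names) && length(set_names) != length(bed_paths))
    stopf("set_names must match bed_paths in length")
  out <- vector("list", length(bed_paths))
  for (i in seq_along(bed_paths)) {
    path <- bed_paths[[i]]
    if (!file.exists(path)) stopf("BED file does not exist: %s", path)
    nm <- set_names[[i]] %||% sub("\\.bed(\\.gz)?$", "", basename(path))
    out[[i]] <- read_one_bed(path, nm)
  }
  nms <- vapply(out, function(x) x$set_name, "")
  if (anyDuplicated(nms)) stopf("duplicate region set names: %s",
                                paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(out) <- nms
  out
}

read_one_bed <- function(path, set_name) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stopf("BED file is empty: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3)) stopf("%s: line %d has fewer than 3 columns",
                            path, which(n_col < 3)[1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) | end0 != floor(end0))
  if (length(bad)) stopf("%s: non-integer coordinates on line %d", path, bad[1])
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad)) stopf("%s: end <= start (or negative start) on line %d", path, bad[1])
  name <- if (all(n_col >= 4)) vapply(fields, `[[`, "", 4L)
          else sprintf("%s_%d", set_name, seq_along(chrom))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0), name = name)
  region_set(set_name, gr, path)
}

region_set <- function(set_name, regions, source_path = NA_character_) {
  stopifnot(nzchar(set_name), length(regions) >= 1)
  structure(list(set_name = set_name, regions = regions, source_path = source_path),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> '%s': %d regions on %d sequence(s)  [%s]\n",
              x$set_name, length(x$regions),
              length(unique(as.character(GenomeInfoDb::seqnames(x$regions)))),
              x$source_path))
  invisible(x)
}

#' Write a region set back to BED
#'
#' @param rs a `region_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(rs, path) {
  gr <- rs$regions
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
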