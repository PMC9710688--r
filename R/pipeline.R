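#' Assemble and validate a per-sample run configuration
#'
#' @param sample_id sample label used in outputs.
#' @param bam coordinate-sorted indexed BAM of the cfDNA sample.
#' @param beds character vector of BED region-set paths.
#' @param fasta indexed reference FASTA.
#' @param bigwig mappability bigWig.
#' @param outdir output directory (a `sample_id` subdirectory is created).
#' @param bin_size,n_bins bin grid, see [build_bin_grid()].
#' @param exclude_center_halfwidth bp excluded from bias training, see
#'   [fit_bias_model()].
#' @param min_mapq,fragment_len_range fragment filters.
#' @param n_norm_windows,norm_window_len background normalization sampling.
#' @param bias_method `"gbm"` or `"lm"`.
#' @param group `"case"`, `"control"` or `"none"`; recorded in outputs and
#'   used by [summarize_runs()].
#' @param seed integer; the single seed all randomness in the run flows from.
#' @return A validated `run_config` list.
#' @export
run_config <- function(sample_id, bam, beds, fasta, bigwig, outdir,
                       bin_size = 500, n_bins = 41,
                       exclude_center_halfwidth = 2000, min_mapq = 20,
                       fragment_len_range = c(70, 400), n_norm_windows = 200,
                       norm_window_len = 1000, bias_method = "gbm",
                       group = "none", seed = 1) {
  for (p in c(bam, beds, fasta, bigwig))
    if (!file.exists(p)) stopf("input file does not exist: %s", p)
  check_bam_index(bam)
  if (!group %in% c("case", "control", "none"))
    stopf("group must be 'case', 'control' or 'none'")
  cfg <- list(sample_id = sample_id, bam = bam, beds = beds, fasta = fasta,
              bigwig = bigwig, outdir = outdir, bin_size = bin_size,
              n_bins = n_bins,
              exclude_center_halfwidth = exclude_center_halfwidth,
              min_mapq = min_mapq, fragment_len_range = fragment_len_range,
              n_norm_windows = n_norm_windows,
              norm_window_len = norm_window_len, bias_method = bias_method,
              group = group, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e)
    stopf("[stage: %s] %s", label, conditionMessage(e)))
}

#' Run the full signature pipeline for one sample
#'
#' Executes, per region set: fragment coverage binning, bias-feature
#' extraction, bias-model fitting and correction, profile aggregation, dip
#' model fitting and scoring.  Writes, under `outdir/sample_id/`: a profile
#' TSV per set (offset, raw and corrected mean/se), a fit JSON per set, a
#' `scores.tsv` across sets, `diagnostics.tsv`, and `log.txt` (package
#' version, config, seed).  Samples are independent computations; a cohort is
#' parallelized by calling this once per sample.
#'
#' @param config a [run_config()].
#' @return A `cfdip_run`: list with `config`, `scores` (data.frame),
#'   `profiles`, `fits`, `diagnostics`, `normalization_factor`, `dir`.
#'   Methods: `print`, `summary`, `plot`.
#' @export
run_sample <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- file.path(config$outdir, config$sample_id)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- build_bin_grid(config$bin_size, config$n_bins)
  sets <- stage("read_region_sets", read_region_sets(config$beds))
  nf <- stage("normalization", estimate_normalization_factor(
    config$bam, n_windows = config$n_norm_windows,
    window_len = config$norm_window_len, seed = config$seed,
    min_mapq = config$min_mapq,
    fragment_len_range = config$fragment_len_range))
  scores <- list(); profiles <- list(); fits <- list(); diags <- list()
  for (rs in sets) {
    nm <- rs$set_name
    cm <- stage(paste0("coverage:", nm), compute_coverage_matrix(
      config$bam, rs, grid, nf, sample_id = config$sample_id,
      min_mapq = config$min_mapq,
      fragment_len_range = config$fragment_len_range))
    fx <- stage(paste0("features:", nm),
                bias_feature_table(config$fasta, config$bigwig, cm))
    bm <- stage(paste0("bias_fit:", nm), fit_bias_model(
      fx, cm, exclude_center_halfwidth = config$exclude_center_halfwidth,
      method = config$bias_method, seed = config$seed))
    ccm <- stage(paste0("bias_correct:", nm),
                 apply_bias_correction(bm, fx, cm))
    sig_raw <- aggregate_profile(cm)
    sig <- stage(paste0("aggregate:", nm), aggregate_profile(ccm))
    fit <- stage(paste0("dip_fit:", nm), fit_dip_model(sig, grid))
    sc <- stage(paste0("scores:", nm), compute_scores(fit, sig, grid))
    sc$holdout_r2 <- bm$holdout_r2
    sc$group <- config$group
    dg <- bias_diagnostics(cm, ccm, fx)
    dg <- cbind(set_name = nm, dg)
    scores[[nm]] <- sc
    profiles[[nm]] <- list(raw = sig_raw, corrected = sig)
    fits[[nm]] <- fit
    diags[[nm]] <- dg
    write.table(data.frame(offset = sig$bin_offsets,
                           mean_corrected = sig$mean_profile,
                           se_corrected = sig$se_profile,
                           mean_raw = sig_raw$mean_profile,
                           se_raw = sig_raw$se_profile),
                file.path(dir, sprintf("profile_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      c(as.list(coef(fit)),
        list(d_se = fit$d_se, rss = fit$rss, converged = fit$converged,
             n_regions_used = fit$n_regions_used, holdout_r2 = bm$holdout_r2,
             seed = config$seed)),
      file.path(dir, sprintf("fit_%s.json", nm)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  score_df <- do.call(rbind, scores)
  rownames(score_df) <- NULL
  diag_df <- do.call(rbind, diags)
  rownames(diag_df) <- NULL
  write.table(score_df, file.path(dir, "scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(diag_df, file.path(dir, "diagnostics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("cfdip %s", as.character(packageVersion("cfdip"))),
               sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("seed: %d", config$seed),
               sprintf("normalization_factor: %.10g", nf),
               "config:",
               paste0("  ", names(config), " = ",
                      vapply(config, function(v) paste(format(v), collapse = ","), ""))),
             file.path(dir, "log.txt"))
  structure(list(config = config, scores = score_df, profiles = profiles,
                 fits = fits, diagnostics = diag_df,
                 normalization_factor = nf, dir = dir),
            class = "cfdip_run")
}

#' @export
print.cfdip_run <- function(x, ...) {
  cat(sprintf("<cfdip_run> sample '%s' (%s), %d region set(s), factor %.4g\n",
              x$config$sample_id, x$config$group, nrow(x$scores),
              x$normalization_factor))
  print(x$scores[, c("set_name", "dip_depth", "dip_sigma", "dip_area",
                     "nonparam_area", "converged")])
  invisible(x)
}

#' @export
summary.cfdip_run <- function(object, ...) {
  cat(sprintf("Sample %s: outputs in %s\n", object$config$sample_id, object$dir))
  print(object$scores)
  cat("\nBias diagnostics:\n")
  print(object$diagnostics)
  invisible(object$scores)
}

#' @export
plot.cfdip_run <- function(x, sets = names(x$fits), ...) {
  for (nm in sets)
    plot(x$fits[[nm]], se_profile = x$profiles[[nm]]$corrected$se_profile, ...)
  invisible(x)
}

#' Merge per-sample scores into a cohort summary, with group testing and plots
#'
#' Reads the `scores.tsv` (and profile TSVs for plotting) from each sample
#' directory written by [run_sample()].  When both case and control samples
#' are present, each case is tested against the control distribution via
#' [compare_to_controls()] and `z`/`p`/`q` columns are populated.  Writes
#' `summary.tsv` plus, per region set, an overlaid mean-profile plot by group
#' and a violin/strip plot of signature strength by group (PDF; plot failures
#' degrade to warnings — the table is the contract).
#'
#' @param score_dirs character vector of per-sample output directories.
#' @param outdir where to write `summary.tsv` and plots; `NULL` skips writing.
#' @param group_labels optional named vector (`sample_id -> label`) overriding
#'   the group recorded in each `scores.tsv`.
#' @param control_label,case_label labels identifying the two groups.
#' @param metric signature-strength metric for testing and violin plots.
#' @return The summary data.frame: one row per (sample, region set) with
#'   `sample_id`, `group`, `set_name`, `dip_depth`, `dip_sigma`, `dip_area`,
#'   `nonparam_area`, `n_regions_used`, `holdout_r2`, `z`, `p`, `q`.
#' @export
summarize_runs <- function(score_dirs, outdir = NULL, group_labels = NULL,
                           control_label = "control", case_label = "case",
                           metric = c("dip_area", "dip_depth",
                                      "nonparam_area")) {
  metric <- match.arg(metric)
  files <- file.path(score_dirs, "scores.tsv")
  ok <- file.exists(files)
  if (!any(ok)) stopf("no score files found under: %s",
                      paste(score_dirs, collapse = ", "))
  if (any(!ok)) warnf("skipping %d directories without scores.tsv", sum(!ok))
  tabs <- lapply(files[ok], read.delim, sep = "\t", stringsAsFactors = FALSE)
  tab <- do.call(rbind, tabs)
  if (!is.null(group_labels))
    tab$group <- unname(group_labels[tab$sample_id])
  dup <- duplicated(tab[, c("sample_id", "set_name")])
  if (any(dup))
    stopf("duplicate (sample, set) rows: %s",
          paste(unique(sprintf("(%s, %s)", tab$sample_id[dup],
                               tab$set_name[dup])), collapse = ", "))
  tab$z <- NA_real_; tab$p <- NA_real_; tab$q <- NA_real_
  has_ctl <- any(tab$group == control_label)
  has_case <- any(tab$group == case_label)
  if (has_ctl && has_case) {
    cmpr <- compare_to_controls(tab[tab$group == case_label, , drop = FALSE],
                                tab[tab$group == control_label, , drop = FALSE],
                                metric = metric)
    key <- paste(tab$sample_id, tab$set_name)
    ckey <- paste(cmpr$sample_id, cmpr$set_name)
    m <- match(key, ckey)
    tab$z <- cmpr$z[m]; tab$p <- cmpr$p[m]; tab$q <- cmpr$q[m]
  }
  out <- tab[, c("sample_id", "group", "set_name", "dip_depth", "dip_sigma",
                 "dip_area", "nonparam_area", "n_regions_used", "holdout_r2",
                 "z", "p", "q")]
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(outdir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tryCatch(write_summary_plots(score_dirs[ok], out, outdir, metric),
             error = function(e) warnf("plotting failed: %s",
                                       conditionMessage(e)))
  }
  out
}
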