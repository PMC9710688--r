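## Per-bin sequence/mappability covariates and the bias regression.
##
## Coverage varies with library and sequencing chemistry through GC content,
## short k-mer composition and alignability.  We model normalized coverage as
## a function of 82 per-bin covariates (GC fraction, 16 dinucleotide and 64
## trinucleotide frequencies, mean mappability), train on bins away from the
## region center so genuine dip signal cannot be absorbed, and subtract the
## predicted technical component.

BIAS_DINUCS <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                               function(a, b) paste0(a, b)))
BIAS_TRINUCS <- as.vector(outer(BIAS_DINUCS, c("A","C","G","T"), paste0))

#' Compute bias features for bin sequences
#'
#' For each bin: GC fraction over non-N bases, dinucleotide and trinucleotide
#' frequencies on the forward strand (k-mers containing N are skipped from
#' both numerator and denominator), and mean per-base mappability.  Bins with
#' more than 10% N (or no informative bases) are flagged masked.
#'
#' @param sequences character vector of bin sequences (uppercase DNA).
#' @param mappability list of per-base numeric vectors (or a single vector
#'   recycled), one per sequence.
#' @return List with `features` (matrix, 82 named columns) and `masked`
#'   (logical vector).
#' @examples
#' compute_bias_features("ACGT", list(rep(1, 4)))$features[, c("gc", "di_AC")]
#' @export
compute_bias_features <- function(sequences, mappability) {
  dna <- Biostrings::DNAStringSet(sequences)
  base <- Biostrings::letterFrequency(dna, c("A", "C", "G", "T", "N"))
  acgt <- rowSums(base[, 1:4, drop = FALSE])
  gc <- ifelse(acgt > 0, (base[, "C"] + base[, "G"]) / acgt, NA_real_)
  din <- Biostrings::oligonucleotideFrequency(dna, 2)[, BIAS_DINUCS, drop = FALSE]
  tri <- Biostrings::oligonucleotideFrequency(dna, 3)[, BIAS_TRINUCS, drop = FALSE]
  din_n <- rowSums(din); tri_n <- rowSums(tri)
  din <- din / ifelse(din_n > 0, din_n, NA_real_)
  tri <- tri / ifelse(tri_n > 0, tri_n, NA_real_)
  if (!is.list(mappability)) mappability <- list(mappability)
  mmap <- vapply(rep_len(mappability, length(sequences)),
                 function(v) mean(v), 0)
  n_frac <- base[, "N"] / pmax(1, Biostrings::width(dna))
  masked <- n_frac > 0.10 | acgt == 0 | din_n == 0 | tri_n == 0
  feats <- cbind(gc = gc, din, tri, map = mmap)
  colnames(feats) <- c("gc", paste0("di_", BIAS_DINUCS),
                       paste0("tri_", BIAS_TRINUCS), "map")
  list(features = feats, masked = masked)
}

#' Build the bias feature table aligned with a coverage matrix
#'
#' One row per (region, bin) cell of the coverage matrix, region-major (all
#' bins of region 1, then region 2, ...), with bin sequences read from the
#' reference FASTA and per-base mappability from the bigWig track.
#'
#' @param fasta_path indexed reference FASTA.
#' @param bigwig_path mappability bigWig.
#' @param cm a `coverage_matrix`.
#' @return A `bias_feature_table`: list with `features` (matrix), `masked`,
#'   `offsets` (bin-center offset of each row, bp), `n_regions`, `grid`.
#' @export
bias_feature_table <- function(fasta_path, bigwig_path, cm) {
  stopifnot(inherits(cm, "coverage_matrix"))
  grid <- cm$grid
  w <- grid$bin_size
  ctr <- region_centers(cm$regions)
  chrom <- as.character(GenomeInfoDb::seqnames(cm$regions))
  n <- length(ctr); k <- grid$n_bins
  bs <- rep(ctr, each = k) + rep(grid$offsets, n) - w / 2   # 0-based bin starts
  bchrom <- rep(chrom, each = k)
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  seqs <- toupper(as.character(Rsamtools::scanFa(fa, GenomicRanges::GRanges(
    bchrom, IRanges::IRanges(bs + 1, bs + w)))))
  map_rows <- mappability_bin_means(bigwig_path, bchrom, bs, w)
  fx <- compute_bias_features(seqs, as.list(rep(1, length(seqs))))
  fx$features[, "map"] <- map_rows
  structure(list(features = fx$features, masked = fx$masked,
                 offsets = rep(grid$offsets, n), n_regions = n, grid = grid),
            class = "bias_feature_table")
}

## Mean mappability per bin, fetched chromosome-wise from the bigWig.
mappability_bin_means <- function(bigwig_path, bchrom, bs, w) {
  bwf <- rtracklayer::BigWigFile(bigwig_path)
  sl <- GenomeInfoDb::seqlengths(bwf)
  out <- numeric(length(bs))
  for (ch in unique(bchrom)) {
    if (!ch %in% names(sl)) stopf("chromosome '%s' not in bigWig", ch)
    sel <- which(bchrom == ch)
    lo <- max(0, min(bs[sel])); hi <- min(sl[[ch]], max(bs[sel]) + w)
    hits <- rtracklayer::import.bw(bwf, which = GenomicRanges::GRanges(
      ch, IRanges::IRanges(lo + 1, hi)))
    v <- numeric(hi - lo)  # missing intervals are 0
    if (length(hits)) {
      a <- pmax(GenomicRanges::start(hits) - 1, lo) - lo
      b <- pmin(GenomicRanges::end(hits), hi) - lo
      for (i in seq_along(hits)) if (b[i] > a[i]) v[(a[i] + 1):b[i]] <- hits$score[i]
    }
    cs <- c(0, cumsum(v))
    s_rel <- pmax(0, pmin(bs[sel] - lo, length(v)))
    e_rel <- pmax(0, pmin(bs[sel] + w - lo, length(v)))
    out[sel] <- (cs[e_rel + 1] - cs[s_rel + 1]) / w
  }
  out
}

#' Fit the technical-bias regression
#'
#' Trains a regressor of normalized coverage on the 82 sequence/mappability
#' features, using only unmasked bins whose center offset lies outside
#' `+/-exclude_center_halfwidth` — the leakage control that keeps the
#' biological dip out of the bias model.  The cross-validated R^2 is reported
#' from a seeded k-fold split of the training rows.
#'
#' @param features a [bias_feature_table()].
#' @param coverage the matching raw `coverage_matrix`.
#' @param exclude_center_halfwidth bp; bins with |offset| <= this are held out
#'   of training (default 2000).
#' @param method `"gbm"` (gradient-boosted trees, the default) or `"lm"`
#'   (ordinary least squares; exact, useful for testing).
#' @param seed integer seed controlling the CV split and the GBM.
#' @param cv_folds number of cross-validation folds (>= 3).
#' @param nrounds,max_depth,eta,min_child_weight,reg_lambda,colsample_bytree
#'   GBM hyperparameters.  Defaults are deliberately conservative (shallow
#'   trees, slow learning, strong leaf regularization, column subsampling):
#'   per-bin coverage is noisy and the technical signal carried by the 82
#'   covariates is weak, so an aggressive booster memorizes noise and shows
#'   negative cross-validated R^2.
#' @return A `bias_model` with elements `method`, `fit`, `training_r2`,
#'   `holdout_r2`, `train_mean`, `excluded_center_halfwidth`.
#' @export
fit_bias_model <- function(features, coverage, exclude_center_halfwidth = 2000,
                           method = c("gbm", "lm"), seed = 1, cv_folds = 3,
                           nrounds = 100, max_depth = 2, eta = 0.05,
                           min_child_weight = 50, reg_lambda = 5,
                           colsample_bytree = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(features, "bias_feature_table"),
            inherits(coverage, "coverage_matrix"), cv_folds >= 3)
  y_all <- as.vector(t(coverage$values))
  if (length(y_all) != nrow(features$features))
    stopf("feature table (%d rows) does not align with coverage matrix (%d cells)",
          nrow(features$features), length(y_all))
  train <- !features$masked & abs(features$offsets) > exclude_center_halfwidth
  if (sum(train) < 200)
    stopf(paste0("only %d training rows after masking/center exclusion ",
                 "(need >= 200); reduce exclude_center_halfwidth or add regions"),
          sum(train))
  X <- features$features[train, , drop = FALSE]
  y <- y_all[train]
  gbm_params <- list(nrounds = nrounds, max_depth = max_depth,
                     learning_rate = eta, min_child_weight = min_child_weight,
                     reg_lambda = reg_lambda,
                     colsample_bytree = colsample_bytree)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), length(y))))
  pred_oof <- numeric(length(y))
  for (f in seq_len(cv_folds)) {
    hold <- folds == f
    fit_f <- fit_regressor(X[!hold, , drop = FALSE], y[!hold], method,
                           seed + f, gbm_params)
    pred_oof[hold] <- predict_regressor(fit_f, X[hold, , drop = FALSE])
  }
  r2 <- function(obs, pred) {  # 0 when there is no variance to explain
    sst <- sum((obs - mean(obs))^2)
    if (sst < 1e-12) 0 else 1 - sum((obs - pred)^2) / sst
  }
  holdout_r2 <- r2(y, pred_oof)
  fit <- fit_regressor(X, y, method, seed, gbm_params)
  pred_in <- predict_regressor(fit, X)
  training_r2 <- r2(y, pred_in)
  structure(list(method = method, fit = fit, training_r2 = training_r2,
                 holdout_r2 = holdout_r2, train_mean = mean(y),
                 excluded_center_halfwidth = exclude_center_halfwidth,
                 seed = seed, n_train = length(y)),
            class = "bias_model")
}

fit_regressor <- function(X, y, method, seed, gbm_params) {
  if (method == "lm") {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0  # collinear columns contribute nothing
    list(kind = "lm", coef = cf)
  } else {
    m <- with_seed(seed, do.call(xgboost::xgboost, c(
      list(x = X, y = y, nthread = 1, verbosity = 0, seed = as.integer(seed)),
      gbm_params)))
    list(kind = "gbm", model = m)
  }
}

predict_regressor <- function(fit, X) {
  if (fit$kind == "lm") as.vector(cbind(1, X) %*% fit$coef)
  else predict(fit$model, X)
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf(
    "<bias_model> %s on %d rows (|offset| > %g bp excluded)\n  R2: training %.3f, %s-fold holdout %.3f; train mean %.4f\n",
    x$method, x$n_train, x$excluded_center_halfwidth, x$training_r2,
    "cv", x$holdout_r2, x$train_mean))
  invisible(x)
}

#' Predict technical coverage for every (region, bin) cell
#'
#' @param object a `bias_model`.
#' @param features a [bias_feature_table()] aligned with the target matrix.
#' @param ... unused.
#' @return Numeric vector, one prediction per feature row (NA for masked rows).
#' @export
predict.bias_model <- function(object, features, ...) {
  p <- rep(NA_real_, nrow(features$features))
  ok <- !features$masked
  p[ok] <- predict_regressor(object$fit, features$features[ok, , drop = FALSE])
  p
}

#' Subtract the predicted technical component from binned coverage
#'
#' `corrected = observed - predicted + train_mean`, applied cell-wise.  The
#' additive form is stable at low-coverage bins where ratios explode.
#' Corrected values may be negative; masked rows become NA and are excluded
#' from downstream aggregation.
#'
#' @param model a fitted `bias_model`.
#' @param features the aligned [bias_feature_table()].
#' @param coverage the raw `coverage_matrix`.
#' @return A corrected `coverage_matrix` (`corrected = TRUE`, with the model
#'   stored in `$bias_model`).
#' @export
apply_bias_correction <- function(model, features, coverage) {
  stopifnot(inherits(model, "bias_model"))
  y <- as.vector(t(coverage$values))
  if (length(y) != nrow(features$features))
    stopf("feature table does not align with coverage matrix")
  pred <- predict(model, features)
  corr <- y - pred + model$train_mean
  out <- coverage
  out$values <- matrix(corr, nrow = nrow(coverage$values),
                       ncol = ncol(coverage$values), byrow = TRUE)
  out$corrected <- TRUE
  out$bias_model <- model
  out
}

#' Before/after bias-correction diagnostics
#'
#' Pearson correlations of coverage with GC and mappability over unmasked
#' cells, before and after correction.  Degenerate (zero-variance) inputs are
#' reported as correlation 0 with `degenerate = TRUE`.
#'
#' @param observed,corrected raw and corrected `coverage_matrix` objects.
#' @param features the aligned [bias_feature_table()].
#' @return data.frame with one row per (covariate, stage) and the holdout R^2
#'   of the model (when available) as attribute `holdout_r2`.
#' @export
bias_diagnostics <- function(observed, corrected, features) {
  y0 <- as.vector(t(observed$values))
  y1 <- as.vector(t(corrected$values))
  ok <- !features$masked & !is.na(y1)
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) c(r = 0, degenerate = 1)
    else c(r = cor(a, b), degenerate = 0)
  }
  gc <- features$features[ok, "gc"]; mp <- features$features[ok, "map"]
  rows <- rbind(
    gc_before = safe_cor(gc, y0[ok]), gc_after = safe_cor(gc, y1[ok]),
    map_before = safe_cor(mp, y0[ok]), map_after = safe_cor(mp, y1[ok]))
  out <- data.frame(covariate = c("gc", "gc", "mappability", "mappability"),
                    stage = c("before", "after", "before", "after"),
                    r = rows[, "r"], degenerate = rows[, "degenerate"] == 1,
                    row.names = NULL)
  attr(out, "holdout_r2") <- corrected$bias_model$holdout_r2 %||% NA_real_
  out
}
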