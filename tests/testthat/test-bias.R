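test_that("bias features count GC and k-mers with the N-skip rule", {
  fx <- compute_bias_features(c("ACGT", "AAAA", "ACNGT", "NNNN"),
                              list(rep(1, 4), rep(0.5, 4), rep(1, 5), rep(1, 4)))
  f <- fx$features
  expect_equal(unname(f[1, "gc"]), 0.5)
  expect_equal(unname(f[1, c("di_AC", "di_CG", "di_GT")]), rep(1 / 3, 3))
  expect_equal(sum(f[1, paste0("di_", cfdip:::BIAS_DINUCS)]), 1)
  expect_equal(sum(f[1, paste0("tri_", cfdip:::BIAS_TRINUCS)]), 1)

  expect_equal(unname(f[2, "gc"]), 0)
  expect_equal(unname(f[2, "di_AA"]), 1)
  expect_equal(unname(f[2, "tri_AAA"]), 1)
  expect_equal(unname(f[2, "map"]), 0.5)

  ## N-containing k-mers are skipped from numerator and denominator
  expect_equal(unname(f[3, c("di_AC", "di_GT")]), c(0.5, 0.5))
  expect_equal(unname(f[3, "di_CG"]), 0)

  expect_false(any(fx$masked[1:2]))
  expect_true(fx$masked[3])   # "ACNGT" is 20% N, over the 10% mask threshold
  expect_true(fx$masked[4])   # all-N bin is masked
})

test_that("the feature table aligns region-major with the coverage matrix", {
  b <- std_bundle()
  rs <- read_region_sets(b$bed)[[1]]
  g <- build_bin_grid(500, 9)
  cm <- compute_coverage_matrix(b$bam, rs, g, 4)
  fx <- bias_feature_table(b$fasta, b$bigwig, cm)
  expect_equal(nrow(fx$features), nrow(cm$values) * g$n_bins)
  expect_equal(fx$offsets[1:g$n_bins], g$offsets)
  expect_false(any(fx$masked))       # simulator genome has no N
  expect_equal(unique(fx$features[, "map"]), 1)  # full-mappability track
  ## spot-check one bin's GC against read_sequence
  ctr <- cfdip:::region_centers(cm$regions)[3]
  ch <- as.character(GenomeInfoDb::seqnames(cm$regions))[3]
  seq <- read_sequence(b$fasta, ch, ctr - 250, ctr + 250)
  gc <- Biostrings::letterFrequency(Biostrings::DNAString(seq), "GC") / 500
  row <- (3 - 1) * g$n_bins + 5     # region 3, center bin
  expect_equal(unname(fx$features[row, "gc"]), unname(gc))
})

test_that("constant coverage fits give constant predictions and near-zero R2", {
  b <- std_bundle()
  rs <- read_region_sets(b$bed)[[1]]
  g <- build_bin_grid(500, 9)
  cm <- compute_coverage_matrix(b$bam, rs, g, 4)
  fx <- bias_feature_table(b$fasta, b$bigwig, cm)
  cm$values[] <- 1.0
  bm <- fit_bias_model(fx, cm, exclude_center_halfwidth = 500, method = "lm",
                       seed = 1)
  pred <- predict(bm, fx)
  expect_equal(unique(round(pred, 10)), 1.0)
  expect_lt(abs(bm$holdout_r2), 0.05)
  expect_equal(bm$train_mean, 1.0)
})

test_that("correction algebra: predicted==observed flattens, predicted==mean is identity", {
  b <- std_bundle()
  rs <- read_region_sets(b$bed)[[1]]
  g <- build_bin_grid(500, 9)
  cm <- compute_coverage_matrix(b$bam, rs, g, 4)
  fx <- bias_feature_table(b$fasta, b$bigwig, cm)
  y <- as.vector(t(cm$values))

  ## coverage lying exactly in the feature span: predicted == observed,
  ## so corrected == train_mean (flat)
  cm_lin <- cm
  cm_lin$values <- matrix(2 + 3 * fx$features[, "gc"], nrow = nrow(cm$values),
                          byrow = TRUE)
  bm_lin <- fit_bias_model(fx, cm_lin, exclude_center_halfwidth = 500,
                           method = "lm", seed = 1)
  corr_lin <- apply_bias_correction(bm_lin, fx, cm_lin)
  expect_equal(unname(corr_lin$values[1, 1]), bm_lin$train_mean,
               tolerance = 1e-8)
  expect_lt(diff(range(corr_lin$values)), 1e-6)

  ## predicted == train_mean (intercept-only model) -> identity correction
  mean_model <- structure(list(method = "lm",
                               fit = list(kind = "lm",
                                          coef = c(`(Intercept)` = mean(y),
                                                   setNames(rep(0, ncol(fx$features)),
                                                            colnames(fx$features)))),
                               train_mean = mean(y), holdout_r2 = NA_real_,
                               training_r2 = NA_real_,
                               excluded_center_halfwidth = 0,
                               n_train = length(y)),
                          class = "bias_model")
  corr <- apply_bias_correction(mean_model, fx, cm)
  expect_equal(corr$values, cm$values, tolerance = 1e-12)  # identity correction
  expect_true(corr$corrected)

  ## algebraic mean identity: mean(corrected) = mean(obs) - mean(pred) + train_mean
  bm <- fit_bias_model(fx, cm, exclude_center_halfwidth = 500, method = "lm",
                       seed = 2)
  corr2 <- apply_bias_correction(bm, fx, cm)
  pred2 <- predict(bm, fx)
  expect_equal(mean(corr2$values), mean(cm$values) - mean(pred2) + bm$train_mean,
               tolerance = 1e-9)
})

test_that("bias fitting is deterministic under a fixed seed", {
  b <- std_bundle()
  rs <- read_region_sets(b$bed)[[1]]
  g <- build_bin_grid(500, 9)
  cm <- compute_coverage_matrix(b$bam, rs, g, 4)
  fx <- bias_feature_table(b$fasta, b$bigwig, cm)
  bm1 <- fit_bias_model(fx, cm, method = "gbm", seed = 5,
                        exclude_center_halfwidth = 500, nrounds = 30)
  bm2 <- fit_bias_model(fx, cm, method = "gbm", seed = 5,
                        exclude_center_halfwidth = 500, nrounds = 30)
  expect_identical(predict(bm1, fx), predict(bm2, fx))
  expect_identical(bm1$holdout_r2, bm2$holdout_r2)
})

test_that("too few training rows give an actionable error", {
  b <- std_bundle()
  rs <- read_region_sets(b$bed)[[1]]
  g <- build_bin_grid(500, 9)
  cm <- compute_coverage_matrix(b$bam, rs, g, 4)
  fx <- bias_feature_table(b$fasta, b$bigwig, cm)
  expect_error(fit_bias_model(fx, cm, exclude_center_halfwidth = 10000),
               "training rows")
  ## shape mismatches are refused
  cm_bad <- cm; cm_bad$values <- cm$values[, 1:5]
  expect_error(fit_bias_model(fx, cm_bad, exclude_center_halfwidth = 500),
               "align")
})

test_that("injected GC bias is detected and removed without inventing signal", {
  cfg <- sim_config(n_regions = 100, mean_coverage = 4, dip_depth = 0,
                    gc_bias = 4, seed = 61)
  b <- cached_bundle("gcbias_fit", cfg)
  rs <- read_region_sets(b$bed)[[1]]
  g <- build_bin_grid(500, 21)
  nf <- estimate_normalization_factor(b$bam, seed = 61)
  cm <- compute_coverage_matrix(b$bam, rs, g, nf)
  fx <- bias_feature_table(b$fasta, b$bigwig, cm)
  bm <- fit_bias_model(fx, cm, exclude_center_halfwidth = 2000, seed = 61)
  expect_gt(bm$holdout_r2, 0)
  ## predicted coverage increases with GC (matches the injected sign)
  pred <- predict(bm, fx)
  expect_gt(cor(fx$features[, "gc"], pred), 0)
  corr <- apply_bias_correction(bm, fx, cm)
  dg <- bias_diagnostics(cm, corr, fx)
  r_before <- abs(dg$r[dg$covariate == "gc" & dg$stage == "before"])
  r_after <- abs(dg$r[dg$covariate == "gc" & dg$stage == "after"])
  expect_lt(r_after, 0.5 * r_before)
})

test_that("diagnostics flag degenerate variance and preserve identity corrections", {
  b <- std_bundle()
  rs <- read_region_sets(b$bed)[[1]]
  g <- build_bin_grid(500, 9)
  cm <- compute_coverage_matrix(b$bam, rs, g, 4)
  fx <- bias_feature_table(b$fasta, b$bigwig, cm)
  dg_same <- bias_diagnostics(cm, cm, fx)
  expect_equal(dg_same$r[dg_same$stage == "before"],
               dg_same$r[dg_same$stage == "after"])
  cm_const <- cm; cm_const$values[] <- 2
  dg_c <- bias_diagnostics(cm_const, cm_const, fx)
  expect_true(all(dg_c$degenerate))
  expect_true(all(dg_c$r == 0))
})
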