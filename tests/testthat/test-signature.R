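test_that("profile aggregation averages rows and propagates SEs", {
  g <- build_bin_grid(100, 5)
  cm <- structure(list(values = rbind(c(0, 2, 0, 2, 0), c(2, 0, 2, 0, 2)),
                       regions = GenomicRanges::GRanges("c1", IRanges::IRanges(1, 10)),
                       dropped = integer(0), grid = g, normalization_factor = 1,
                       set_name = "t", sample_id = "s", corrected = TRUE),
                  class = "coverage_matrix")
  sig <- aggregate_profile(cm)
  expect_equal(sig$mean_profile, rep(1, 5))
  expect_equal(sig$se_profile, rep(1, 5))  # sd sqrt(2), /sqrt(2)

  cm$values <- rbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  sig2 <- aggregate_profile(cm)
  expect_equal(sig2$mean_profile, 1:5)
  expect_equal(sig2$se_profile, rep(0, 5))

  ## NA cells are excluded per column; an all-NA column errors
  cm$values[1, 2] <- NA
  expect_equal(aggregate_profile(cm)$mean_profile[2], 2)
  cm$values[, 3] <- NA
  expect_error(aggregate_profile(cm), "no unmasked")
})

test_that("the dip model inverts a noise-free profile to 1e-3", {
  g <- build_bin_grid(500, 41)
  y <- 1.0 - 0.3 * exp(-g$offsets^2 / (2 * 1500^2))
  fit <- fit_dip_model(profile_signature(g$offsets, y, g))
  expect_true(fit$converged)
  p <- coef(fit)
  expect_equal(unname(p["d"]), 0.3, tolerance = 1e-3)
  expect_equal(unname(p["sigma"]), 1500, tolerance = 1e-3 * 1500)
  expect_equal(unname(p["b0"]), 1.0, tolerance = 1e-3)
  expect_lt(fit$rss, 1e-10)
  ## fitted/residuals/predict are consistent
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
  expect_equal(predict(fit, 0), unname(p["b0"]) - unname(p["d"]),
               tolerance = 1e-6)
})

test_that("a sloping baseline with a dip is separated into its parts", {
  g <- build_bin_grid(500, 41)
  x <- g$offsets
  y <- 1.2 + 2e-5 * x + 3e-9 * x^2 - 0.25 * exp(-x^2 / (2 * 2000^2))
  fit <- fit_dip_model(profile_signature(x, y, g))
  p <- coef(fit)
  expect_equal(unname(p["d"]), 0.25, tolerance = 0.01)
  expect_equal(unname(p["sigma"]), 2000, tolerance = 20)
  expect_equal(unname(p["b1"]), 2e-5, tolerance = 1e-6)
})

test_that("a flat profile yields an essentially zero dip", {
  g <- build_bin_grid(500, 41)
  fit <- fit_dip_model(profile_signature(g$offsets, rep(1, 41), g))
  p <- coef(fit)
  expect_lte(unname(p["d"]), 1e-6)
  expect_equal(unname(p["b0"]), 1.0, tolerance = 1e-6)
  expect_true(is.finite(fit$d_se))

  expect_error(fit_dip_model(profile_signature(0:7 * 500, rep(1, 8),
                                               build_bin_grid(500, 5))),
               "too coarse")
})

test_that("signature scores match closed forms and numeric integration", {
  g <- build_bin_grid(500, 41)
  y <- 1.0 - 0.3 * exp(-g$offsets^2 / (2 * 1500^2))
  sig <- profile_signature(g$offsets, y, g)
  fit <- fit_dip_model(sig)
  sc <- compute_scores(fit, sig, g)
  expect_equal(sc$dip_area, 0.3 * 1500 * sqrt(2 * pi), tolerance = 0.01 * 1128)
  expect_equal(sc$dip_area, 1128.3, tolerance = 1)

  ## numeric integration of the fitted Gaussian over a wide grid agrees to 1%
  p <- coef(fit)
  xx <- seq(-g$half_span, g$half_span, by = 1)
  num <- sum(p["d"] * exp(-xx^2 / (2 * p["sigma"]^2)))
  expect_gte(g$half_span, 4 * p[["sigma"]])
  expect_lt(abs(sc$dip_area - num) / num, 0.01)

  ## flat profile: nonparametric area is exactly zero
  sigf <- profile_signature(g$offsets, rep(1, 41), g)
  scf <- compute_scores(fit_dip_model(sigf), sigf, g)
  expect_equal(scf$nonparam_area, 0)

  ## inverted signature gives negative nonparametric area
  sigi <- profile_signature(g$offsets, 1 + 0.2 * exp(-g$offsets^2 / (2 * 1500^2)), g)
  sci <- compute_scores(fit_dip_model(sigi), sigi, g)
  expect_lt(sci$nonparam_area, 0)
})

test_that("unconverged fits fall back to nonparametric metrics", {
  g <- build_bin_grid(500, 41)
  y <- 1.0 - 0.3 * exp(-g$offsets^2 / (2 * 1500^2))
  sig <- profile_signature(g$offsets, y, g)
  fit <- fit_dip_model(sig)
  fit$converged <- FALSE
  sc <- compute_scores(fit, sig, g)
  expect_true(is.na(sc$dip_depth) && is.na(sc$dip_area))
  expect_gt(sc$nonparam_area, 0)
})

test_that("z-scores against controls follow the normal closed forms", {
  mk <- function(id, set, v)
    data.frame(sample_id = id, set_name = set, dip_area = v,
               dip_depth = v / 1000, nonparam_area = v)
  ctl <- mk(sprintf("c%d", 1:5), "s1", c(8, 10, 12, 10, 10))
  mu <- mean(ctl$dip_area); sdv <- sd(ctl$dip_area)
  case <- rbind(mk("k1", "s1", mu), mk("k2", "s1", mu + 2 * sdv))
  cmp <- compare_to_controls(case, ctl)
  expect_equal(cmp$z, c(0, 2))
  expect_equal(cmp$p[1], 1)
  expect_equal(cmp$p[2], 0.0455, tolerance = 1e-3)
  expect_equal(cmp$n_controls, c(5, 5))

  ## BH adjustment across sets within a sample
  ctl2 <- rbind(mk(sprintf("c%d", 1:5), "s1", c(8, 10, 12, 10, 10)),
                mk(sprintf("c%d", 1:5), "s2", c(3, 4, 5, 4, 4)))
  case2 <- rbind(mk("k1", "s1", mu + 2 * sdv), mk("k1", "s2", 4))
  cmp2 <- compare_to_controls(case2, ctl2)
  expect_equal(sort(cmp2$q),
               sort(p.adjust(cmp2$p, "BH")))

  ## degenerate control SD
  ctl0 <- mk(sprintf("c%d", 1:4), "s1", rep(7, 4))
  cmp0 <- compare_to_controls(mk("k", "s1", 9), ctl0)
  expect_true(cmp0$degenerate)
  expect_true(is.na(cmp0$z))

  expect_error(compare_to_controls(mk("k", "s1", 1), mk("c", "s1", 1)),
               ">= 3 controls")
})

test_that("dip area increases with simulated dip depth (matched seeds)", {
  ## same seed -> same genome/regions/noise realization; only the dip differs
  scores <- vapply(c(0.1, 0.4), function(dd) {
    b <- cached_bundle(sprintf("mono%g", dd),
                       sim_config(n_regions = 50, mean_coverage = 4,
                                  dip_depth = dd, seed = 314))
    rs <- read_region_sets(b$bed)[[1]]
    g <- build_bin_grid(500, 41)
    nf <- estimate_normalization_factor(b$bam, seed = 314)
    cm <- compute_coverage_matrix(b$bam, rs, g, nf)
    sig <- aggregate_profile(cm)
    sc <- compute_scores(fit_dip_model(sig), sig, g)
    sc$dip_area
  }, 0)
  expect_true(all(diff(scores) > 0))
  expect_equal(scores[2] / scores[1], 4, tolerance = 1.2)
})
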