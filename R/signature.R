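#' Aggregate a coverage matrix into a per-sample signature profile
#'
#' Column-wise mean and standard error of the (corrected) coverage matrix over
#' retained regions; missing entries (masked bins) are excluded per column.
#' A 10% trimmed mean is available to guard against outlier regions.
#'
#' @param cm a `coverage_matrix` (typically bias-corrected).
#' @param trim trimming fraction per tail for the mean (default 0, i.e.
#'   unweighted mean; 0.1 gives the 10% trimmed mean).
#' @return An `agg_signature`: list with `set_name`, `sample_id`,
#'   `bin_offsets`, `mean_profile`, `se_profile`, `n_regions_used`, `grid`.
#' @export
aggregate_profile <- function(cm, trim = 0) {
  stopifnot(inherits(cm, "coverage_matrix"), nrow(cm$values) >= 1)
  v <- cm$values
  n_ok <- colSums(!is.na(v))
  if (any(n_ok == 0))
    stopf("bin(s) at offset %s have no unmasked regions",
          paste(cm$grid$offsets[n_ok == 0], collapse = ", "))
  mp <- apply(v, 2, mean, trim = trim, na.rm = TRUE)
  se <- apply(v, 2, sd, na.rm = TRUE) / sqrt(n_ok)
  se[is.na(se)] <- 0  # single-region sets
  structure(list(set_name = cm$set_name, sample_id = cm$sample_id,
                 bin_offsets = cm$grid$offsets, mean_profile = unname(mp),
                 se_profile = unname(se), n_regions_used = nrow(v),
                 grid = cm$grid),
            class = "agg_signature")
}

#' @export
print.agg_signature <- function(x, ...) {
  cat(sprintf("<agg_signature> %s / %s: %d bins over %d regions; center %.3f, flank %.3f\n",
              x$sample_id, x$set_name, length(x$mean_profile), x$n_regions_used,
              x$mean_profile[(length(x$mean_profile) + 1) / 2],
              mean(x$mean_profile[c(1, length(x$mean_profile))])))
  invisible(x)
}

## Gaussian dip on a quadratic baseline; x in kb internally for conditioning.
dip_curve <- function(p, x) {
  p <- unname(p)
  p[1] + p[2] * x + p[3] * x^2 - p[4] * exp(-x^2 / (2 * p[5]^2))
}

#' Fit the parametric dip model to an aggregated profile
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt) of
#' `y(x) = b0 + b1 x + b2 x^2 - d exp(-x^2 / (2 sigma^2))`
#' against the mean profile over bin-center offsets `x` (bp).  The quadratic
#' baseline absorbs sloping background; the Gaussian term carries the
#' nucleosome-footprint dip with depth `d >= 0` (coverage units) and scale
#' `sigma` bounded to `[bin_size, half_span]`.  Initialization: `b0` = mean of
#' the outer 25% of bins, `b1 = b2 = 0`, `d = b0 - min(profile)`,
#' `sigma = 1000` bp.
#'
#' @param signature an [aggregate_profile()] result (or any list with
#'   `bin_offsets` and `mean_profile`).
#' @param grid the [build_bin_grid()] grid (taken from `signature` if absent).
#' @return A `dip_fit` with coefficients `b0`, `b1` (per bp), `b2` (per bp^2),
#'   `d`, `sigma` (bp), plus `d_se`, `rss`, `baseline_rss`, `converged`, and
#'   the data used.  Methods: `print`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `summary`.
#' @export
fit_dip_model <- function(signature, grid = NULL) {
  grid <- grid %||% signature$grid
  x_bp <- signature$bin_offsets
  y <- signature$mean_profile
  k <- length(y)
  if (k < 9) stopf("grid too coarse for dip fit (need >= 9 bins, have %d)", k)
  x <- x_bp / 1000  # kb internally
  outer_idx <- abs(x_bp) >= stats::quantile(abs(x_bp), 0.75)
  b0_init <- mean(y[outer_idx])
  p0 <- c(b0 = b0_init, b1 = 0, b2 = 0, d = max(b0_init - min(y), 0), s = 1)
  lower <- c(-Inf, -Inf, -Inf, 0, grid$bin_size / 1000)
  upper <- c(Inf, Inf, Inf, Inf, grid$half_span / 1000)
  p0[5] <- min(max(p0[5], lower[5]), upper[5])
  res <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = function(p) y - dip_curve(p, x),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  pfit <- coef(res)
  rss <- sum(res$fvec^2)
  base_fit <- stats::lm.fit(cbind(1, x, x^2), y)
  baseline_rss <- sum(base_fit$residuals^2)
  converged <- res$info %in% 1:4 && rss <= baseline_rss * (1 + 1e-8) + 1e-12
  d_se <- dip_d_se(res, pfit, x, length(y))
  out <- list(coefficients = c(b0 = unname(pfit[1]), b1 = unname(pfit[2]) / 1000,
                               b2 = unname(pfit[3]) / 1e6, d = unname(pfit[4]),
                               sigma = unname(pfit[5]) * 1000),
              d_se = d_se, rss = rss, baseline_rss = baseline_rss,
              converged = converged, info = res$info,
              n_regions_used = signature$n_regions_used %||% NA_integer_,
              x = x_bp, y = y, grid = grid,
              set_name = signature$set_name %||% NA_character_,
              sample_id = signature$sample_id %||% NA_character_)
  class(out) <- "dip_fit"
  out
}

## Standard error of d from the LM Jacobian; pseudoinverse fallback covers
## the boundary case d = 0 where the hessian is singular.
dip_d_se <- function(res, pfit, x, n) {
  se <- tryCatch(sqrt(diag(vcov(res))["d"]), error = function(e) NA_real_)
  if (is.finite(se)) return(unname(se))
  eps <- 1e-6
  J <- vapply(seq_along(pfit), function(j) {
    ph <- pfit; ph[j] <- ph[j] + eps
    (dip_curve(ph, x) - dip_curve(pfit, x)) / eps
  }, numeric(length(x)))
  s2 <- sum(res$fvec^2) / max(1, n - length(pfit))
  cv <- s2 * MASS::ginv(crossprod(J))
  se <- sqrt(max(cv[4, 4], 0))
  if (!is.finite(se) || se == 0) se <- sqrt(s2)  # flat-profile floor
  unname(se)
}

#' @export
coef.dip_fit <- function(object, ...) object$coefficients

#' @export
fitted.dip_fit <- function(object, ...) {
  p <- object$coefficients
  dip_curve(c(p[1], p[2] * 1000, p[3] * 1e6, p[4], p[5] / 1000), object$x / 1000)
}

#' @export
residuals.dip_fit <- function(object, ...) object$y - fitted(object)

#' Predict the fitted dip model at new offsets
#'
#' @param object a `dip_fit`.
#' @param newdata numeric vector of offsets in bp (defaults to the fitted
#'   grid).
#' @param ... unused.
#' @export
predict.dip_fit <- function(object, newdata = NULL, ...) {
  xbp <- newdata %||% object$x
  p <- object$coefficients
  dip_curve(c(p[1], p[2] * 1000, p[3] * 1e6, p[4], p[5] / 1000), xbp / 1000)
}

#' @export
print.dip_fit <- function(x, ...) {
  p <- x$coefficients
  cat(sprintf("<dip_fit> %s / %s%s\n",
              x$sample_id, x$set_name,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  depth d = %.4f (se %.4f), sigma = %.0f bp, baseline b0 = %.4f\n",
              p["d"], x$d_se, p["sigma"], p["b0"]))
  cat(sprintf("  rss %.4g (baseline-only %.4g), %d bins\n",
              x$rss, x$baseline_rss, length(x$y)))
  invisible(x)
}

#' @export
summary.dip_fit <- function(object, ...) {
  structure(list(fit = object,
                 r2 = 1 - object$rss / sum((object$y - mean(object$y))^2)),
            class = "summary.dip_fit")
}

#' @export
print.summary.dip_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  model R2 over bins: %.4f\n", x$r2))
  invisible(x)
}

#' Plot an aggregated profile with its fitted dip model
#'
#' @param x a `dip_fit`.
#' @param se_profile optional per-bin standard errors to draw as a band.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dip_fit <- function(x, se_profile = NULL, ...) {
  graphics::plot(x$x, x$y, pch = 16, cex = 0.7,
                 xlab = "distance to region center (bp)",
                 ylab = "normalized coverage",
                 main = sprintf("%s / %s", x$sample_id, x$set_name), ...)
  if (!is.null(se_profile)) {
    graphics::arrows(x$x, x$y - se_profile, x$x, x$y + se_profile,
                     angle = 90, code = 3, length = 0.02, col = "grey60")
  }
  xx <- seq(min(x$x), max(x$x), length.out = 400)
  graphics::lines(xx, predict(x, xx), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Signature-strength metrics from a fitted dip model
#'
#' `dip_depth` is the fitted `d`; `dip_area = d * sigma * sqrt(2*pi)`
#' (coverage x bp), the analytic area of the Gaussian dip; `nonparam_area` is
#' the model-free fallback: flank baseline minus profile, summed over central
#' bins (|offset| <= half_span/2) times bin size, with the flank baseline the
#' mean over bins with |offset| > 3/4 half_span.  For unconverged fits the
#' parametric metrics are NA and only `nonparam_area` is reported.  A negative
#' `nonparam_area` flags an inverted signature.
#'
#' @param fit a [fit_dip_model()] result.
#' @param signature the matching [aggregate_profile()] result.
#' @param grid the bin grid (defaults to the one in `fit`).
#' @return A `signature_score`: one-row data.frame with `sample_id`,
#'   `set_name`, `dip_depth`, `dip_sigma`, `dip_area`, `nonparam_area`,
#'   `d_se`, `converged`, `n_regions_used`, `holdout_r2` (NA unless set by
#'   the pipeline).
#' @export
compute_scores <- function(fit, signature, grid = NULL) {
  grid <- grid %||% fit$grid
  stopifnot(inherits(fit, "dip_fit"),
            length(signature$mean_profile) == grid$n_bins)
  off <- signature$bin_offsets
  central <- abs(off) <= grid$half_span / 2
  flank <- abs(off) > 3 * grid$half_span / 4
  flank_mean <- mean(signature$mean_profile[flank])
  npa <- sum(flank_mean - signature$mean_profile[central]) * grid$bin_size
  p <- coef(fit)
  if (fit$converged) {
    dd <- unname(p["d"]); ds <- unname(p["sigma"])
    da <- dd * ds * sqrt(2 * pi)
  } else {
    dd <- NA_real_; ds <- NA_real_; da <- NA_real_
  }
  out <- data.frame(sample_id = fit$sample_id, set_name = fit$set_name,
                    dip_depth = dd, dip_sigma = ds, dip_area = da,
                    nonparam_area = npa, d_se = fit$d_se,
                    converged = fit$converged,
                    n_regions_used = signature$n_regions_used,
                    holdout_r2 = NA_real_)
  class(out) <- c("signature_score", "data.frame")
  out
}

#' Test case samples against a control group
#'
#' For each case sample and region set, the z-score of its signature-strength
#' metric against the control distribution
#' (`z = (score - control_mean) / control_sd`) with a two-sided normal
#' p-value; when one sample is tested across several region sets, q-values
#' are Benjamini-Hochberg-adjusted across sets within the sample.  Requires
#' at least 3 controls with finite values; a zero control SD marks the
#' comparison degenerate (no z).
#'
#' @param case_scores,control_scores data.frames of `signature_score` rows
#'   (rbind-ed as needed).
#' @param metric which column to test: `"dip_area"` (default), `"dip_depth"`
#'   or `"nonparam_area"`.
#' @return data.frame with one row per (case sample, set): `sample_id`,
#'   `set_name`, `metric`, `score`, `control_mean`, `control_sd`,
#'   `n_controls`, `z`, `p`, `q`, `degenerate`.
#' @export
compare_to_controls <- function(case_scores, control_scores,
                                metric = c("dip_area", "dip_depth",
                                           "nonparam_area")) {
  metric <- match.arg(metric)
  case_scores <- as.data.frame(case_scores)
  control_scores <- as.data.frame(control_scores)
  out <- list()
  for (set in unique(case_scores$set_name)) {
    ctl <- control_scores[control_scores$set_name == set, metric]
    ctl <- ctl[is.finite(ctl)]
    if (length(ctl) < 3)
      stopf("need >= 3 controls with finite '%s' for set '%s' (have %d)",
            metric, set, length(ctl))
    mu <- mean(ctl); s <- sd(ctl)
    cs <- case_scores[case_scores$set_name == set, , drop = FALSE]
    deg <- s == 0
    z <- if (deg) rep(NA_real_, nrow(cs)) else (cs[[metric]] - mu) / s
    out[[set]] <- data.frame(sample_id = cs$sample_id, set_name = set,
                             metric = metric, score = cs[[metric]],
                             control_mean = mu, control_sd = s,
                             n_controls = length(ctl), z = z,
                             p = 2 * pnorm(-abs(z)), degenerate = deg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$q <- NA_real_
  for (sid in unique(res$sample_id)) {
    sel <- res$sample_id == sid & !is.na(res$p)
    res$q[sel] <- p.adjust(res$p[sel], method = "BH")
  }
  res
}
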