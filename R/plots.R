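## Cohort plots: overlaid mean profiles by group and violin/strip plots of
## signature strength.  Base graphics, written as vector PDF; tables remain
## the contract, plots are a convenience.

group_palette <- function(groups) {
  pal <- c("#2166AC", "#B2182B", "#4D4D4D", "#1B7837", "#762A83")
  setNames(rep_len(pal, length(groups)), groups)
}

#' Overlay per-sample aggregated profiles by group
#'
#' @param profiles named list: `sample_id -> data.frame(offset, mean)`.
#' @param groups named vector `sample_id -> group`.
#' @param main plot title.
#' @export
plot_profile_overlay <- function(profiles, groups, main = "") {
  cols <- group_palette(unique(groups))
  xr <- range(unlist(lapply(profiles, `[[`, "offset")))
  yr <- range(unlist(lapply(profiles, `[[`, "mean")))
  graphics::plot(NA, xlim = xr, ylim = yr,
                 xlab = "distance to region center (bp)",
                 ylab = "bias-corrected normalized coverage", main = main)
  for (sid in names(profiles))
    graphics::lines(profiles[[sid]]$offset, profiles[[sid]]$mean,
                    col = cols[[groups[[sid]]]], lwd = 1.5)
  graphics::legend("bottomright", legend = names(cols), col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(NULL)
}

#' Violin/strip plot of signature strength by group
#'
#' Density-outline violins (when a group has >= 3 distinct values) with
#' jittered points on top.
#'
#' @param values numeric vector of the metric.
#' @param groups character vector of group labels, same length.
#' @param main,ylab plot annotation.
#' @export
plot_strength_violin <- function(values, groups, main = "", ylab = "dip area") {
  gl <- unique(groups)
  cols <- group_palette(gl)
  graphics::plot(NA, xlim = c(0.5, length(gl) + 0.5), ylim = range(values),
                 xaxt = "n", xlab = "", ylab = ylab, main = main)
  graphics::axis(1, at = seq_along(gl), labels = gl)
  for (i in seq_along(gl)) {
    v <- values[groups == gl[i]]
    if (length(unique(v)) >= 3) {
      d <- stats::density(v)
      wd <- 0.35 * d$y / max(d$y)
      graphics::polygon(c(i - wd, rev(i + wd)), c(d$x, rev(d$x)),
                        col = grDevices::adjustcolor(cols[[gl[i]]], 0.3),
                        border = cols[[gl[i]]])
    }
    graphics::points(i + seq(-0.08, 0.08, length.out = length(v)), v,
                     pch = 16, col = cols[[gl[i]]])
  }
  invisible(NULL)
}

## Called by summarize_runs(): one profile-overlay and one violin page per
## region set.
write_summary_plots <- function(sample_dirs, summary_tab, outdir, metric) {
  for (set in unique(summary_tab$set_name)) {
    sub <- summary_tab[summary_tab$set_name == set, , drop = FALSE]
    profs <- list()
    for (i in seq_len(nrow(sub))) {
      f <- file.path(sample_dirs[basename(sample_dirs) == sub$sample_id[i]],
                     sprintf("profile_%s.tsv", set))
      if (length(f) == 1 && file.exists(f)) {
        p <- read.delim(f)
        profs[[sub$sample_id[i]]] <- data.frame(offset = p$offset,
                                                mean = p$mean_corrected)
      }
    }
    grp <- setNames(sub$group, sub$sample_id)
    pdf_path <- file.path(outdir, sprintf("summary_%s.pdf", set))
    grDevices::pdf(pdf_path, width = 9, height = 4.5)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(1, 2))
    if (length(profs)) plot_profile_overlay(profs, grp, main = set)
    ok <- is.finite(sub[[metric]])
    if (any(ok)) plot_strength_violin(sub[[metric]][ok], sub$group[ok],
                                      main = set, ylab = metric)
    grDevices::dev.off()
    on.exit()
  }
  invisible(NULL)
}
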