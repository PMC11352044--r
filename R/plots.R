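# Base-graphics displays for fitted objects and experiment reports.

#' Plot fold-change estimates of a single fit
#'
#' Barplot of the signed fold change per method, with the true value (when
#' known) as a dashed reference line.
#'
#' @param x A `"fold_change"` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.fold_change <- function(x, ...) {
  res <- x$results
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(stats::setNames(res$fc, res$method), las = 2,
                    ylab = "signed fold change",
                    main = res$variable_id[1], ...)
  if (!is.null(x$fc_true)) {
    graphics::abline(h = signed_fold(x$fc_true), lty = 2)
  }
  invisible(x)
}

#' Plot an experiment report
#'
#' Dispatches on the experiment id: a family-by-method heatmap of mean
#' absolute recovery error for the distribution stress test; per-panel
#' error-versus-fold-change curves for the variance sweep; a volcano plot
#' with crossover connectors for the significance panels; a between-method
#' correlation image for the permutation stress.
#'
#' @param x An `"fc_experiment"`.
#' @param ... Unused.
#' @export
plot.fc_experiment <- function(x, ...) {
  switch(x$experiment_id,
    distribution_stress = plot_stress(x),
    variance_sweep = plot_sweep(x),
    significance_panel = plot_significance(x),
    permutation_stress = plot_permutation(x),
    stop("no plot method for experiment '", x$experiment_id, "'"))
  invisible(x)
}

plot_stress <- function(x) {
  s <- x$summary[x$summary$transform == "raw" &
                 x$summary$n == max(x$summary$n), ]
  fam <- unique(s$family)
  met <- unique(s$method)
  z <- matrix(NA_real_, length(fam), length(met), dimnames = list(fam, met))
  for (i in seq_len(nrow(s))) z[s$family[i], s$method[i]] <- abs(s$error_mean[i])
  op <- graphics::par(mar = c(10, 11, 3, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  graphics::image(seq_along(met), seq_along(fam), t(log1p(z)), col = pal,
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("|mean ErrorFC| (log1p scale), n = %d",
                                 max(x$summary$n)))
  graphics::axis(1, seq_along(met), met, las = 2)
  graphics::axis(2, seq_along(fam), fam, las = 1)
  graphics::box()
}

plot_sweep <- function(x) {
  s <- x$summary
  panels <- unique(s[c("s_a", "s_ratio")])
  panels <- panels[order(panels$s_a, panels$s_ratio), ]
  methods <- unique(s$method)
  op <- graphics::par(mfrow = c(length(unique(panels$s_a)),
                                length(unique(panels$s_ratio))),
                      mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(op))
  for (i in seq_len(nrow(panels))) {
    sub <- s[s$s_a == panels$s_a[i] & s$s_ratio == panels$s_ratio[i], ]
    ylim <- range(sub$error_mean, 0, finite = TRUE)
    graphics::plot(NA, xlim = range(sub$fc_true), ylim = ylim,
                   xlab = "true FC", ylab = "mean ErrorFC",
                   main = sprintf("s_a=%g, s_b/s_a=%g", panels$s_a[i],
                                  panels$s_ratio[i]), cex.main = 0.9)
    graphics::abline(h = 0, col = "grey70")
    for (j in seq_along(methods)) {
      mm <- sub[sub$method == methods[j], ]
      mm <- mm[order(mm$fc_true), ]
      graphics::lines(mm$fc_true, mm$error_mean, col = j, lwd = 1.5)
    }
  }
  graphics::legend("topright", legend = methods, col = seq_along(methods),
                   lwd = 1.5, cex = 0.7, bg = "white")
}

plot_significance <- function(x) {
  volcano_plot(x$cells, crossovers = x$crossovers)
}

plot_permutation <- function(x) {
  mc <- x$method_correlation[x$method_correlation$matrix == "permuted", ]
  met <- unique(c(mc$method_1, mc$method_2))
  z <- matrix(1, length(met), length(met), dimnames = list(met, met))
  for (i in seq_len(nrow(mc))) {
    z[mc$method_1[i], mc$method_2[i]] <- mc$rho[i]
    z[mc$method_2[i], mc$method_1[i]] <- mc$rho[i]
  }
  op <- graphics::par(mar = c(11, 11, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_along(met), seq_along(met), z,
                  zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "between-method Spearman rho (permuted matrix)")
  graphics::axis(1, seq_along(met), met, las = 2)
  graphics::axis(2, seq_along(met), met, las = 1)
  for (i in seq_along(met)) for (j in seq_along(met)) {
    graphics::text(i, j, sprintf("%.2f", z[i, j]), cex = 0.7)
  }
  graphics::box()
}

#' Volcano plot comparing two fold-change estimators
#'
#' Scatter of `-log10 p` against the log2 fold change for two estimation
#' methods, with segments connecting the two positions of each variable;
#' crossover variables (regulation direction flips between the methods)
#' are highlighted.
#'
#' @param tbl Tidy table from [fc_significance_table()] (a `family` column
#'   is honoured by faceting into one panel per family).
#' @param methods The two methods to contrast.
#' @param test Which test's p-values to use for the y axis.
#' @param crossovers Optional crossover table as produced by
#'   [run_significance_panel()].
#' @export
volcano_plot <- function(tbl, methods = c("log_of_means", "mean_of_logs"),
                         test = "wilcoxon", crossovers = NULL) {
  methods <- match_fc_method(methods)
  stopifnot(length(methods) == 2L)
  fams <- if ("family" %in% names(tbl)) unique(tbl$family) else NA
  op <- graphics::par(mfrow = c(1, length(fams)),
                      mar = c(4, 4, 3, 1), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(op))
  for (fam in fams) {
    sub <- if (is.na(fam[1])) tbl else tbl[tbl$family == fam, ]
    sub <- sub[sub$test == test, ]
    m1 <- sub[sub$method == methods[1], ]
    m2 <- sub[sub$method == methods[2], ]
    m2 <- m2[match(m1$variable_id, m2$variable_id), ]
    xlim <- range(c(m1$log_ratio, m2$log_ratio), finite = TRUE)
    ylim <- range(c(m1$neg_log10_p), finite = TRUE)
    graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "log2 FC",
                   ylab = "-log10 p",
                   main = if (is.na(fam[1])) "volcano" else paste("volcano:", fam))
    graphics::segments(m1$log_ratio, m1$neg_log10_p, m2$log_ratio,
                       m2$neg_log10_p, col = "grey75")
    graphics::points(m1$log_ratio, m1$neg_log10_p, pch = 16, col = "steelblue")
    graphics::points(m2$log_ratio, m2$neg_log10_p, pch = 17, col = "tomato")
    graphics::abline(v = 0, lty = 3)
    if (!is.null(crossovers) && nrow(crossovers)) {
      co <- if (is.na(fam[1])) crossovers else
        crossovers[crossovers$family == fam, ]
      hit <- m1$variable_id %in% co$variable_id
      if (any(hit)) {
        graphics::points(m1$log_ratio[hit], m1$neg_log10_p[hit], pch = 1,
                         cex = 2, col = "black", lwd = 2)
      }
    }
    graphics::legend("topleft", legend = methods, pch = c(16, 17),
                     col = c("steelblue", "tomato"), cex = 0.8, bg = "white")
  }
  invisible(tbl)
}
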