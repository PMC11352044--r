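# The four reproducible simulation studies.  Each returns an
# "fc_experiment": tidy per-replicate cells plus aggregated summaries, with
# every generating seed recorded so any cell can be recomputed on its own.

new_experiment <- function(id, cells, params, ...) {
  structure(c(list(experiment_id = id, cells = cells, params = params),
              list(...)),
            class = "fc_experiment")
}

#' @export
print.fc_experiment <- function(x, ...) {
  cat(sprintf("fc_experiment '%s': %d cell rows\n", x$experiment_id,
              nrow(x$cells)))
  extras <- setdiff(names(x), c("experiment_id", "cells", "params"))
  for (e in extras) {
    if (is.data.frame(x[[e]])) {
      cat(sprintf("  $%s: %d x %d\n", e, nrow(x[[e]]), ncol(x[[e]])))
    }
  }
  cat("  params:", paste(names(x$params), unlist(lapply(x$params, function(p)
    paste(format(unlist(p)), collapse = ","))), sep = "=", collapse = "  "), "\n")
  invisible(x)
}

# Safe per-cell estimation: failures become records, not aborts.
cell_log_ratio <- function(sample, method, bootstrap_reps, seed,
                           values_a = NULL, values_b = NULL) {
  a <- values_a %||% sample$a
  b <- values_b %||% sample$b
  tryCatch(
    list(log_ratio = log_ratio(a, b, method, bootstrap_reps = bootstrap_reps,
                               seed = seed, variable_id = sample$variable_id),
         failed = FALSE, message = NA_character_),
    error = function(e) list(log_ratio = NA_real_, failed = TRUE,
                             message = conditionMessage(e)))
}

#' Distribution stress test of fold-change recovery
#'
#' Generates two-group data under every distribution family (identity,
#' uniform, normal, log-normal, the two family-crossed mixtures and the
#' per-element mixture), at each sample size in `n_levels`, and scores how
#' well each estimator recovers the known true ratio via [error_fc()].
#' Optionally repeats all calculations on log2-re-transformed data
#' (emulating fold changes computed accidentally on already-logged
#' pipeline output); on that scale the recovered values are no longer
#' "times expression", so no error against `fc_true` is attributed there.
#'
#' @param n_levels Integer vector of group sizes (default 10 and 10000: a
#'   small-sample and a large-sample regime).
#' @param reps Monte-Carlo replicates per cell; cells report per-replicate
#'   values plus the mean.
#' @param fc_true True ratio used throughout.
#' @param m_a Reference location.
#' @param s_normal Standard deviation used for normal-family groups
#'   (measurement units).
#' @param s_lognormal Log-scale standard deviation for log-normal groups
#'   (also used for the per-element `mixed` family).
#' @param methods,bootstrap_reps See [fold_change()].
#' @param relog Also run the log2-re-transformed variant.
#' @param seed Master seed; all per-cell seeds derive from it.
#' @return An `"fc_experiment"` with `cells` (one row per family x n x
#'   replicate x transform x method) and `summary` (per-cell means of the
#'   signed and absolute errors, with failure counts).
#' @export
run_distribution_stress <- function(n_levels = c(10L, 10000L), reps = 25L,
                                    fc_true = 2, m_a = 100, s_normal = 10,
                                    s_lognormal = 1,
                                    methods = fc_methods(),
                                    bootstrap_reps = 100L, relog = TRUE,
                                    seed = NULL) {
  methods <- match_fc_method(methods)
  families <- c("identity", "uniform", "normal", "lognormal",
                "mixed_normal_lognormal", "mixed_lognormal_normal", "mixed")
  fam_s <- function(fam) switch(fam,
    identity = c(0, 0), uniform = c(0, 0),
    normal = c(s_normal, s_normal),
    lognormal = c(s_lognormal, s_lognormal),
    mixed_normal_lognormal = c(s_normal, s_lognormal),
    mixed_lognormal_normal = c(s_lognormal, s_normal),
    mixed = c(s_lognormal, s_lognormal))
  grid <- expand.grid(family = families, n = n_levels, rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, 2L * nrow(grid))
  grid$seed <- seeds[seq_len(nrow(grid))]
  boot_seeds <- seeds[-seq_len(nrow(grid))]
  transforms <- if (relog) c("raw", "relog") else "raw"

  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- fam_s(grid$family[i])
    smp <- generate_sample(sim_spec(grid$family[i], m_a = m_a,
                                    fc_true = fc_true, s_a = s[1], s_b = s[2],
                                    n_a = grid$n[i], n_b = grid$n[i],
                                    seed = grid$seed[i]))
    rows <- lapply(transforms, function(tr) {
      va <- if (tr == "relog") log2(smp$a) else NULL
      vb <- if (tr == "relog") log2(smp$b) else NULL
      res <- lapply(seq_along(methods), function(j) {
        r <- cell_log_ratio(smp, methods[j], bootstrap_reps,
                            seed = boot_seeds[i] + j, values_a = va,
                            values_b = vb)
        data.frame(family = grid$family[i], n = grid$n[i], rep = grid$rep[i],
                   seed = grid$seed[i], transform = tr, method = methods[j],
                   log_ratio = r$log_ratio,
                   fc = if (r$failed) NA_real_ else fc_from_log_ratio(r$log_ratio),
                   error = if (r$failed || tr == "relog") NA_real_ else
                     error_fc(fc_from_log_ratio(r$log_ratio), fc_true),
                   failed = r$failed, message = r$message,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    })
    cells[[i]] <- do.call(rbind, rows)
  }
  cells <- do.call(rbind, cells)

  agg <- stats::aggregate(
    cbind(error_mean = error, abs_error_mean = abs(error)) ~
      family + n + transform + method,
    data = cells[cells$transform == "raw", ], FUN = mean, na.action = stats::na.omit)
  fails <- stats::aggregate(failed ~ family + n + transform + method,
                            data = cells, FUN = sum)
  names(fails)[names(fails) == "failed"] <- "n_failed"
  summary <- merge(agg, fails, all = TRUE,
                   by = c("family", "n", "transform", "method"))

  new_experiment("distribution_stress", cells,
                 params = list(n_levels = n_levels, reps = reps,
                               fc_true = fc_true, m_a = m_a,
                               s_normal = s_normal,
                               s_lognormal = s_lognormal, methods = methods,
                               bootstrap_reps = bootstrap_reps,
                               relog = relog, seed = seed),
                 summary = summary)
}

#' Variance-ratio sweep on log-normal data
#'
#' Sweeps true fold change and the treatment/reference spread ratio on
#' log-normal two-group data and quantifies each estimator's recovery error.
#' The defaults are the canonical study grids: a 20-point fold-change grid
#' spanning 0.1 to 6, spread ratios `s_b/s_a` of 0.1, 0.5, 1, 2, 4, 8 and
#' reference spreads 0.1 and 1 (natural-log scale).
#'
#' Each cell row carries, besides the signed [error_fc()], the log2-ratio
#' error `lr_error`, the closed-form expectation bias of the
#' arithmetic-mean method `(s_b^2 - s_a^2) / (2 ln 2)` bits (valid for
#' `log_of_means` in the regime where the sample mean is converged), and
#' the fold-magnitude error `|fc_calculated| - |fc_true|` on the signed
#' fold scale, whose sign flips at FC = 1 for the arithmetic-mean method
#' under unequal spreads (over-estimation of the fold magnitude below 1,
#' under-estimation above, when `s_b < s_a`).
#'
#' The bootstrap estimators are excluded from the default method set here
#' purely for speed; pass them explicitly if wanted.
#'
#' @param fc_grid,s_ratio_grid,s_a_levels,n,m_a See [generate_sweep()].
#' @param reps Monte-Carlo replicates per grid cell.
#' @param methods,bootstrap_reps See [fold_change()].
#' @param seed Master seed.
#' @return An `"fc_experiment"` with `cells`, per-cell `summary`
#'   (means of the error columns), and `trends` (per-panel OLS slope and
#'   intercept of the signed error against `fc_true`, as in the usual
#'   error-versus-fold-change panel display).
#' @export
run_variance_sweep <- function(fc_grid = seq(0.1, 6, length.out = 20),
                               s_ratio_grid = c(0.1, 0.5, 1, 2, 4, 8),
                               s_a_levels = c(0.1, 1),
                               n = 10000L, reps = 25L, m_a = 100,
                               methods = setdiff(fc_methods(),
                                                 c("pairs_mean_bootstrap",
                                                   "pairs_median_bootstrap")),
                               bootstrap_reps = 100L, seed = NULL) {
  methods <- match_fc_method(methods)
  rep_seeds <- derive_seeds(seed, reps)
  cells <- vector("list", reps)
  for (r in seq_len(reps)) {
    sweep <- generate_sweep(fc_grid, s_ratio_grid, s_a_levels, n = n,
                            m_a = m_a, seed = rep_seeds[r])
    g <- sweep$grid
    rows <- lapply(seq_len(nrow(g)), function(i) {
      smp <- sweep$samples[[i]]
      lr <- vapply(methods, function(m) {
        res <- cell_log_ratio(smp, m, bootstrap_reps, seed = g$seed[i])
        res$log_ratio
      }, numeric(1))
      fc <- fc_from_log_ratio(lr)
      data.frame(fc_true = g$fc_true[i], s_ratio = g$s_ratio[i],
                 s_a = g$s_a[i], s_b = g$s_b[i], rep = r, seed = g$seed[i],
                 method = methods, log_ratio = lr, fc = fc,
                 error = error_fc(fc, g$fc_true[i]),
                 lr_error = lr - log2(g$fc_true[i]),
                 predicted_lr_bias = (g$s_b[i]^2 - g$s_a[i]^2) / (2 * log(2)),
                 mag_error = abs(signed_fold(fc)) -
                   abs(signed_fold(g$fc_true[i])),
                 stringsAsFactors = FALSE)
    })
    cells[[r]] <- do.call(rbind, rows)
  }
  cells <- do.call(rbind, cells)

  summary <- stats::aggregate(
    cbind(error_mean = error, abs_error_mean = abs(error),
          lr_error_mean = lr_error, mag_error_mean = mag_error) ~
      method + s_a + s_ratio + fc_true, data = cells, FUN = mean)
  pred <- unique(cells[c("method", "s_a", "s_ratio", "s_b", "fc_true",
                         "predicted_lr_bias")])
  summary <- merge(summary, pred,
                   by = c("method", "s_a", "s_ratio", "fc_true"))

  panels <- unique(cells[c("method", "s_a", "s_ratio")])
  trends <- do.call(rbind, lapply(seq_len(nrow(panels)), function(i) {
    sub <- cells[cells$method == panels$method[i] &
                 cells$s_a == panels$s_a[i] &
                 cells$s_ratio == panels$s_ratio[i], ]
    fit <- stats::lm(error ~ fc_true, data = sub)
    data.frame(method = panels$method[i], s_a = panels$s_a[i],
               s_ratio = panels$s_ratio[i],
               intercept = unname(stats::coef(fit)[1]),
               slope = unname(stats::coef(fit)[2]),
               stringsAsFactors = FALSE)
  }))

  new_experiment("variance_sweep", cells,
                 params = list(fc_grid = fc_grid,
                               s_ratio_grid = s_ratio_grid,
                               s_a_levels = s_a_levels, n = n, reps = reps,
                               m_a = m_a, methods = methods, seed = seed),
                 summary = summary, trends = trends)
}

#' Effect-size / significance concordance panels with crossover detection
#'
#' Generates one multi-variable panel per requested family, computes the
#' volcano table (all methods x both tests), the Spearman concordance of
#' `|log2 FC|` with `-log10 p` per method and test, the concordance of
#' `|log2 FC|` with the true `|log2 FC|`, and flags crossover variables:
#' variables whose regulation direction flips between two estimators
#' (both log2 ratios beyond `crossover_min_lr` bits, signs opposite).
#'
#' @param d Number of variables per panel.
#' @param families Panel families to generate (subset of
#'   `c("normal", "lognormal", "mixed")`).
#' @param n_a,n_b Group sizes.
#' @param methods,tests,bootstrap_reps See [fc_significance_table()].
#' @param crossover_methods Pair of method identifiers compared for sign
#'   flips (default arithmetic mean versus geometric mean).
#' @param crossover_min_lr Minimum `|log2 ratio|` (bits) under both
#'   methods for a variable to count as a crossover, guarding against
#'   sign flips at numerical zero.
#' @param seed Master seed.
#' @param ... Passed to [panel_spec()] (parameter ranges).
#' @return An `"fc_experiment"` with `cells` (volcano rows per family),
#'   `correlations` (rho of `|log2 FC|` vs `-log10 p` and vs the truth),
#'   `crossovers`, and `panel_meta` (the generating per-variable
#'   parameters).
#' @export
run_significance_panel <- function(d = 99L,
                                   families = c("normal", "lognormal"),
                                   n_a = 50L, n_b = 50L,
                                   methods = fc_methods(),
                                   tests = c("wilcoxon", "t"),
                                   bootstrap_reps = 100L,
                                   crossover_methods = c("log_of_means",
                                                         "mean_of_logs"),
                                   crossover_min_lr = 0.1, seed = NULL,
                                   ...) {
  methods <- match_fc_method(methods)
  crossover_methods <- match_fc_method(crossover_methods)
  stopifnot(length(crossover_methods) == 2L)
  fam_seeds <- derive_seeds(seed, 2L * length(families))
  cells <- NULL; correlations <- NULL; crossovers <- NULL; panel_meta <- NULL
  for (k in seq_along(families)) {
    fam <- families[k]
    panel <- generate_panel(panel_spec(d = d, family = fam, n_a = n_a,
                                       n_b = n_b, seed = fam_seeds[k], ...))
    tbl <- suppressWarnings(
      fc_significance_table(panel, methods = methods, tests = tests,
                            bootstrap_reps = bootstrap_reps,
                            seed = fam_seeds[length(families) + k],
                            on_error = "na"))
    tbl$family <- fam
    cells <- rbind(cells, tbl)
    meta <- panel$meta
    meta$family_panel <- fam
    panel_meta <- rbind(panel_meta, meta)

    rho <- spearman_fc_significance(tbl)
    rho$family <- fam
    truth <- stats::setNames(abs(log2(meta$fc_true)), meta$variable_id)
    rho$rho_vs_true <- vapply(seq_len(nrow(rho)), function(i) {
      sub <- tbl[tbl$method == rho$method[i] & tbl$test == rho$test[i], ]
      suppressWarnings(stats::cor(abs(sub$log_ratio),
                                  truth[sub$variable_id],
                                  method = "spearman",
                                  use = "complete.obs"))
    }, numeric(1))
    correlations <- rbind(correlations, rho)

    one <- tbl[tbl$test == tbl$test[1L], ]
    lr1 <- stats::setNames(
      one$log_ratio[one$method == crossover_methods[1]],
      one$variable_id[one$method == crossover_methods[1]])
    lr2 <- stats::setNames(
      one$log_ratio[one$method == crossover_methods[2]],
      one$variable_id[one$method == crossover_methods[2]])
    ids <- intersect(names(lr1), names(lr2))
    flip <- ids[which(sign(lr1[ids]) != sign(lr2[ids]) &
                      abs(lr1[ids]) > crossover_min_lr &
                      abs(lr2[ids]) > crossover_min_lr)]
    if (length(flip)) {
      crossovers <- rbind(crossovers, data.frame(
        family = fam, variable_id = flip,
        log_ratio_1 = unname(lr1[flip]), log_ratio_2 = unname(lr2[flip]),
        method_1 = crossover_methods[1], method_2 = crossover_methods[2],
        stringsAsFactors = FALSE))
    }
  }
  new_experiment("significance_panel", cells,
                 params = list(d = d, families = families, n_a = n_a,
                               n_b = n_b, methods = methods, tests = tests,
                               crossover_methods = crossover_methods,
                               crossover_min_lr = crossover_min_lr,
                               seed = seed),
                 correlations = correlations,
                 crossovers = crossovers %||% data.frame(),
                 panel_meta = panel_meta)
}

#' Whole-matrix permutation stress comparison
#'
#' Computes fold changes (all requested methods) and both significance
#' tests on a variables-by-samples matrix twice: as given, and after a
#' global permutation of every matrix entry across both dimensions.  The
#' permutation preserves the pooled value multiset but turns every
#' variable's per-group distribution into an arbitrary mixture of the whole
#' matrix, which is the hostile regime for moment-based estimators.
#' Reported are between-method Spearman correlations of `|log2 FC|`, each
#' method's concordance with the Wilcoxon `-log10 p`, and pooled plus
#' per-variable skewness/kurtosis.
#'
#' @param x Variables-by-samples numeric matrix or `"variable_panel"`.
#' @param labels Group labels (ignored for panels).
#' @param methods,tests,bootstrap_reps See [fc_significance_table()].
#' @param seed Seed for the permutation and the bootstrap estimators.
#' @return An `"fc_experiment"` with `cells` (volcano rows for the original
#'   and the permuted matrix), `method_correlation` (tidy between-method
#'   rho per matrix state), `significance_correlation`, and `moments`.
#' @export
run_permutation_stress <- function(x, labels = NULL,
                                   methods = fc_methods(),
                                   tests = c("wilcoxon", "t"),
                                   bootstrap_reps = 100L, seed = NULL) {
  if (inherits(x, "variable_panel")) {
    labels <- panel_labels(x)
    x <- as.matrix(x)
  }
  lab <- check_labels(x, labels)
  methods <- match_fc_method(methods)
  seeds <- derive_seeds(seed, 3L)
  perm <- permute_matrix(x, seed = seeds[1L])

  state_tbl <- function(mat, state, s) {
    tbl <- suppressWarnings(
      fc_significance_table(mat, lab, methods = methods, tests = tests,
                            bootstrap_reps = bootstrap_reps, seed = s,
                            on_error = "na"))
    tbl$matrix <- state
    tbl
  }
  cells <- rbind(state_tbl(x, "original", seeds[2L]),
                 state_tbl(perm, "permuted", seeds[3L]))

  method_correlation <- NULL
  significance_correlation <- NULL
  for (state in c("original", "permuted")) {
    sub <- cells[cells$matrix == state & cells$test == tests[1L], ]
    lrm <- do.call(cbind, lapply(methods, function(m)
      abs(sub$log_ratio[sub$method == m])))
    colnames(lrm) <- methods
    cm <- suppressWarnings(stats::cor(lrm, method = "spearman",
                                      use = "pairwise.complete.obs"))
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    method_correlation <- rbind(method_correlation, data.frame(
      matrix = state, method_1 = methods[idx[, 1]],
      method_2 = methods[idx[, 2]], rho = cm[idx],
      stringsAsFactors = FALSE))
    wil <- cells[cells$matrix == state & cells$test == "wilcoxon", ]
    if (nrow(wil)) {
      sc <- spearman_fc_significance(wil)
      sc$matrix <- state
      significance_correlation <- rbind(significance_correlation, sc)
    }
  }

  var_moments <- function(mat) {
    data.frame(
      skewness = apply(mat, 1L, e1071::skewness),
      kurtosis = apply(mat, 1L, e1071::kurtosis))
  }
  mom <- function(mat, state) {
    vm <- var_moments(mat)
    data.frame(matrix = state,
               pooled_skewness = e1071::skewness(as.vector(mat)),
               pooled_kurtosis = e1071::kurtosis(as.vector(mat)),
               mean_variable_skewness = mean(vm$skewness, na.rm = TRUE),
               max_variable_skewness = max(vm$skewness, na.rm = TRUE),
               mean_variable_kurtosis = mean(vm$kurtosis, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  moments <- rbind(mom(x, "original"), mom(perm, "permuted"))

  new_experiment("permutation_stress", cells,
                 params = list(d = nrow(x), n_a = sum(lab == "reference"),
                               n_b = sum(lab == "treatment"),
                               methods = methods, tests = tests,
                               seed = seed),
                 method_correlation = method_correlation,
                 significance_correlation = significance_correlation,
                 moments = moments, permuted = perm)
}
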