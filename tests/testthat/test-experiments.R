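# small-scale runs of the four studies; the full-scale study conditions are
# exercised in test-acceptance.R

test_that("distribution stress reports exact recovery on deterministic data", {
  ex <- run_distribution_stress(n_levels = c(10L, 400L), reps = 3L,
                                seed = 41)
  expect_s3_class(ex, "fc_experiment")
  idn <- ex$summary[ex$summary$family == "identity" &
                    ex$summary$transform == "raw", ]
  expect_equal(idn$error_mean, rep(0, nrow(idn)), tolerance = 1e-9)
  # cells carry everything needed to recompute any entry
  expect_true(all(c("family", "n", "rep", "seed", "transform", "method",
                    "log_ratio", "error", "failed") %in% names(ex$cells)))
  # the relog variant never gets an error attributed against fc_true
  expect_true(all(is.na(ex$cells$error[ex$cells$transform == "relog"])))
})

test_that("experiments rerun identically from the same master seed", {
  e1 <- run_distribution_stress(n_levels = 50L, reps = 2L, relog = FALSE,
                                methods = c("log_of_means", "pairs_median"),
                                seed = 42)
  e2 <- run_distribution_stress(n_levels = 50L, reps = 2L, relog = FALSE,
                                methods = c("log_of_means", "pairs_median"),
                                seed = 42)
  expect_identical(e1$cells, e2$cells)
  s1 <- run_variance_sweep(fc_grid = c(0.5, 2), s_ratio_grid = c(0.5, 1),
                           s_a_levels = 0.1, n = 100L, reps = 2L,
                           methods = "log_of_means", seed = 43)
  s2 <- run_variance_sweep(fc_grid = c(0.5, 2), s_ratio_grid = c(0.5, 1),
                           s_a_levels = 0.1, n = 100L, reps = 2L,
                           methods = "log_of_means", seed = 43)
  expect_identical(s1$cells, s2$cells)
  # any single cell is recomputable from its recorded spec + seed
  row <- s1$cells[5, ]
  smp <- generate_sample(sim_spec("lognormal", m_a = 100,
                                  fc_true = row$fc_true, s_a = row$s_a,
                                  s_b = row$s_b, n_a = 100, n_b = 100,
                                  seed = row$seed))
  expect_equal(log_ratio(smp$a, smp$b, row$method), row$log_ratio)
})

test_that("per-cell failures are recorded instead of aborting the grid", {
  # tiny m with a large normal spread forces non-positive draws
  ex <- run_distribution_stress(n_levels = 200L, reps = 2L, m_a = 5,
                                s_normal = 10, relog = FALSE,
                                methods = c("log_of_means", "mean_of_logs"),
                                seed = 44)
  failed <- ex$cells[ex$cells$failed, ]
  expect_gt(nrow(failed), 0)
  expect_true(all(grepl("positive", failed$message)))
  expect_true(all(is.na(failed$log_ratio)))
  expect_gt(sum(ex$summary$n_failed), 0)
})

test_that("the sweep is unbiased with a flat trend when spreads are equal", {
  sw <- run_variance_sweep(fc_grid = seq(0.5, 4, length.out = 6),
                           s_ratio_grid = 1, s_a_levels = 0.1, n = 2000L,
                           reps = 3L, methods = c("log_of_means",
                                                  "mean_of_logs"),
                           seed = 45)
  expect_lt(max(abs(sw$summary$error_mean)), 0.05)
  expect_lt(max(abs(sw$trends$slope)), 0.02)
  expect_true(all(sw$summary$predicted_lr_bias == 0))
})

test_that("relogging preserves variable rankings on clean data", {
  # identity panel: each variable a distinct constant pair
  fcs <- seq(0.4, 3, length.out = 12)
  x <- t(sapply(fcs, function(f) c(rep(10, 6), rep(10 * f, 6))))
  rownames(x) <- paste0("v", seq_along(fcs))
  colnames(x) <- paste0("s", 1:12)
  lab <- setNames(rep(c("reference", "treatment"), each = 6), colnames(x))
  raw <- fold_change_matrix(x, lab, methods = "log_of_medians")
  rel <- fold_change_matrix(log2(x * 4), lab, methods = "log_of_medians")
  expect_equal(cor(raw$log_ratio, rel$log_ratio, method = "spearman"), 1)
  # normal panel: rankings survive to rho > 0.9
  set.seed(46)
  xn <- t(sapply(fcs, function(f)
    c(rnorm(40, 100, 8), rnorm(40, 100 * f, 8))))
  rownames(xn) <- paste0("v", seq_along(fcs))
  colnames(xn) <- paste0("s", 1:80)
  labn <- setNames(rep(c("reference", "treatment"), each = 40), colnames(xn))
  raw_n <- fold_change_matrix(xn, labn, methods = "mean_of_logs")
  rel_n <- fold_change_matrix(log2(xn), labn, methods = "mean_of_logs")
  expect_gt(cor(raw_n$log_ratio, rel_n$log_ratio, method = "spearman"), 0.9)
})

test_that("significance panels report correlations, truth recovery and shapes", {
  ex <- run_significance_panel(d = 15L, families = "normal", n_a = 20L,
                               n_b = 20L,
                               methods = c("log_of_means", "mean_of_logs",
                                           "pairs_median"),
                               seed = 47)
  expect_equal(nrow(ex$correlations), 3 * 2)
  expect_true(all(c("rho", "rho_vs_true") %in% names(ex$correlations)))
  expect_true(all(ex$correlations$rho_vs_true > 0))
  expect_equal(nrow(ex$panel_meta), 15)
  expect_equal(nrow(ex$cells), 15 * 3 * 2)
})

test_that("crossovers need opposite signs beyond the magnitude floor", {
  ex <- run_significance_panel(d = 25L, families = "lognormal", n_a = 25L,
                               n_b = 25L,
                               methods = c("log_of_means", "mean_of_logs"),
                               tests = "wilcoxon", seed = 48)
  co <- ex$crossovers
  if (nrow(co)) {
    expect_true(all(sign(co$log_ratio_1) != sign(co$log_ratio_2)))
    expect_true(all(abs(co$log_ratio_1) > 0.1 & abs(co$log_ratio_2) > 0.1))
  }
  # raising the floor can only reduce the count
  ex2 <- run_significance_panel(d = 25L, families = "lognormal", n_a = 25L,
                                n_b = 25L,
                                methods = c("log_of_means", "mean_of_logs"),
                                tests = "wilcoxon", crossover_min_lr = 2,
                                seed = 48)
  expect_lte(nrow(ex2$crossovers), nrow(co))
})

test_that("permutation stress conserves values and reports correlations", {
  p <- generate_panel(panel_spec(d = 30L, family = "lognormal", n_a = 15L,
                                 n_b = 15L, seed = 49))
  ex <- run_permutation_stress(p, methods = c("log_of_means",
                                              "mean_of_logs",
                                              "pairs_median"),
                               seed = 50)
  m <- as.matrix(p)
  expect_identical(sort(as.vector(ex$permuted)), sort(as.vector(m)))
  expect_equal(ex$moments$pooled_skewness[1], ex$moments$pooled_skewness[2])
  expect_equal(ex$moments$pooled_kurtosis[1], ex$moments$pooled_kurtosis[2])
  expect_equal(nrow(ex$method_correlation), 2 * 3)  # 2 states x choose(3,2)
  expect_setequal(unique(ex$cells$matrix), c("original", "permuted"))
  expect_true(all(ex$significance_correlation$test == "wilcoxon"))
})

test_that("estimators agree tightly on an unpermuted all-normal panel", {
  p <- generate_panel(panel_spec(d = 40L, family = "normal", n_a = 30L,
                                 n_b = 30L, seed = 51))
  ex <- run_permutation_stress(p, methods = c("log_of_means",
                                              "log_of_medians",
                                              "mean_of_logs",
                                              "pairs_median"),
                               tests = "wilcoxon", seed = 52)
  orig <- ex$method_correlation[ex$method_correlation$matrix == "original", ]
  expect_true(all(orig$rho > 0.95))
})
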