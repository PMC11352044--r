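test_that("a three-fold increase gives log2 ratio 1.585 under every method", {
  a <- c(1, 1, 1)
  b <- c(3, 3, 3)
  for (m in fc_methods()) {
    expect_equal(log_ratio(a, b, m, seed = 1), log2(3), tolerance = 1e-12,
                 label = m)
  }
  expect_equal(round(log_ratio(a, b, "log_of_means"), 2), 1.58)
  # one-third-fold is the mirror image
  expect_equal(round(log_ratio(b, a, "mean_of_logs"), 2), -1.58)
})

test_that("identical groups give zero log ratio for all eight methods", {
  a <- c(5, 7, 9)
  boot <- c("pairs_mean_bootstrap", "pairs_median_bootstrap")
  for (m in setdiff(fc_methods(), boot)) {
    expect_equal(log_ratio(a, a, m, seed = 3), 0, tolerance = 1e-12, label = m)
  }
  # resampling the two groups independently leaves only bootstrap noise,
  # which shrinks with the replicate count
  for (m in boot) {
    expect_equal(log_ratio(a, a, m, bootstrap_reps = 400L, seed = 3), 0,
                 tolerance = 0.1, label = m)
  }
})

test_that("pairwise and mean-based methods agree with hand arithmetic on {1,2} vs {4,8}", {
  a <- c(1, 2)
  b <- c(4, 8)
  # cross-pair log2 ratios are {2, 3, 1, 2}: mean 2, median 2
  expect_equal(log_ratio(a, b, "pairs_mean"), 2)
  expect_equal(log_ratio(a, b, "pairs_median"), 2)
  expect_equal(log_ratio(a, b, "log_of_means"), 2)   # log2(6/1.5)
  expect_equal(log_ratio(a, b, "mean_of_logs"), 2)   # (2+3)/2 - (0+1)/2
  expect_equal(brute_pairs_lr(a, b, "mean"), 2)
  expect_equal(brute_pairs_lr(a, b, "median"), 2)
})

test_that("degenerate constant groups recover the exact fold for all methods", {
  fit <- fold_change(rep(2, 100), rep(6, 100), seed = 11)
  expect_s3_class(fit, "fold_change")
  expect_equal(nrow(fit$results), 8L)
  expect_equal(round(fit$results$log_ratio, 3), rep(1.585, 8))
  expect_equal(unname(coef(fit, type = "fc")), rep(3, 8), tolerance = 1e-9)
})

test_that("signed fold conversion follows the branch form and round-trips", {
  expect_identical(fc_from_log_ratio(0), 1)
  expect_equal(fc_from_log_ratio(1.58496), 3, tolerance = 1e-4)
  expect_equal(fc_from_log_ratio(-1.58496), -3, tolerance = 1e-4)
  lr <- seq(-6, 6, by = 0.37)
  lr <- lr[lr != 0]
  # the two printed forms of the conversion agree away from zero
  expect_equal(fc_from_log_ratio(lr), 2^abs(lr) * sign(lr), tolerance = 1e-12)
  expect_equal(log_ratio_from_fc(fc_from_log_ratio(lr)), lr, tolerance = 1e-12)
  expect_error(fc_from_log_ratio(Inf), "finite")
  expect_error(fc_from_log_ratio(NA_real_), "finite")
})

test_that("the fold-change error metric matches direct arithmetic and is antisymmetric", {
  expect_identical(error_fc(0.5, 0.5), 0)
  expect_equal(error_fc(2, 3), -1)
  expect_equal(error_fc(0.5, 2), -4)     # (-2) - (+2)
  expect_equal(error_fc(1/3, 1), -4)     # ratio input: 1/3 means -3-fold
  expect_equal(error_fc(-3, 1), -4)      # signed-fold input, same answer
  set.seed(42)
  x <- exp(runif(50, -2, 2))
  y <- exp(runif(50, -2, 2))
  expect_equal(error_fc(x, y), -error_fc(y, x), tolerance = 1e-12)
  expect_equal(error_fc(x, x), rep(0, 50))
  expect_error(error_fc(-0.5, 2), "positive ratio")
  expect_error(error_fc(2, 0), "finite|positive")
})

test_that("log-domain methods reject non-positive or empty input, naming the variable", {
  expect_error(log_ratio(c(1, 0, 2), c(3, 3), "mean_of_logs",
                         variable_id = "CRP"),
               "positive.*CRP")
  expect_error(log_ratio(c(1, 2), c(-3, 3), "log_of_means"), "positive")
  expect_error(log_ratio(numeric(0), c(1, 2), "log_of_means"),
               "at least one observation")
  expect_error(fold_change(numeric(0), c(1, 2)), "at least one observation")
  expect_error(log_ratio(c(1, 2), c(3, 4), "banana"),
               "unknown fold-change method.*pairs_median")
})

test_that("the geometric-mean alias resolves to mean_of_logs", {
  a <- rlnorm(20, 2, 1)
  b <- rlnorm(20, 2.5, 1)
  expect_identical(log_ratio(a, b, "geometric_mean"),
                   log_ratio(a, b, "mean_of_logs"))
})

test_that("the formula interface matches the two-vector interface", {
  set.seed(8)
  df <- data.frame(value = rlnorm(40, 3, 0.5),
                   group = rep(c("ctrl", "case"), each = 20))
  f1 <- fold_change(value ~ group, data = df, reference = "ctrl",
                    methods = "mean_of_logs")
  f2 <- fold_change(df$value[df$group == "ctrl"],
                    df$value[df$group == "case"], methods = "mean_of_logs")
  expect_equal(coef(f1), coef(f2))
  expect_error(fold_change(value ~ group, data = df, reference = "nope"),
               "reference level")
  df$group3 <- rep(c("a", "b", "c"), length.out = 40)
  expect_error(fold_change(value ~ group3, data = df), "two levels")
})

test_that("fold_change carries the recovery error when the truth is known", {
  fit <- fold_change(rep(10, 5), rep(30, 5), fc_true = 3,
                     methods = c("log_of_means", "pairs_median"))
  expect_equal(fit$results$error, c(0, 0), tolerance = 1e-9)
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("true ratio", out)))
})

test_that("matrix-wide estimation is tidy and failure-tolerant on demand", {
  x <- rbind(g1 = c(1, 2, 4, 8), g2 = c(10, 10, 30, 30),
             g3 = c(5, -1, 5, 7))
  colnames(x) <- paste0("s", 1:4)
  lab <- setNames(rep(c("reference", "treatment"), each = 2), colnames(x))
  expect_error(fold_change_matrix(x, lab, methods = "mean_of_logs"),
               "positive.*g3")
  expect_warning(
    tbl <- fold_change_matrix(x, lab, methods = c("log_of_means",
                                                  "mean_of_logs"),
                              on_error = "na"),
    "1 variable")
  expect_equal(nrow(tbl), 6L)
  expect_true(all(is.na(tbl$log_ratio[tbl$variable_id == "g3"])))
  expect_equal(tbl$log_ratio[tbl$variable_id == "g2" &
                             tbl$method == "log_of_means"], log2(3))
  # label validation
  expect_error(fold_change_matrix(x, lab[1:3]), "missing from labels.*s4")
  expect_error(fold_change_matrix(x, rep("reference", 4)),
               "both a reference and a treatment")
  expect_error(fold_change_matrix(x, c(lab[1:3], s4 = "banana")), "banana")
})
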