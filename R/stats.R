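#' Two-group significance test
#'
#' Compares reference and treatment measurements of one variable with either
#' the Wilcoxon-Mann-Whitney rank-sum test (nonparametric, invariant under
#' monotone transforms of the pooled data) or the t-test (parametric;
#' Welch's unequal-variance form by default, pooled-variance Student form
#' via `var_equal = TRUE`).  Two-sided throughout; rank ties are handled by
#' the usual mid-rank correction.
#'
#' A degenerate comparison (constant pooled data) yields `p_value = 1` with
#' `degenerate = TRUE` rather than an error, so matrix-wide scans never
#' abort on flat variables.
#'
#' @param a Reference measurements, or a [grouped_sample()] (then `b` is
#'   taken from it).
#' @param b Treatment measurements.
#' @param test `"wilcoxon"` or `"t"`.
#' @param var_equal For the t-test: use the pooled-variance form.
#' @param variable_id Optional label carried into the result.
#' @return A one-row data frame: `variable_id`, `test`, `statistic`,
#'   `p_value`, `neg_log10_p` (`= -log10(p_value)`), `degenerate`.
#' @examples
#' compare_groups(c(1, 2, 3), c(101, 102, 103), test = "wilcoxon")  # p = 0.1
#' @export
compare_groups <- function(a, b = NULL, test = c("wilcoxon", "t"),
                           var_equal = FALSE, variable_id = NULL) {
  if (inherits(a, "grouped_sample")) {
    variable_id <- variable_id %||% a$variable_id
    b <- a$b
    a <- a$a
  }
  test <- match.arg(test)
  variable_id <- variable_id %||% "V1"
  check_groups(a, b, variable_id, log_domain = FALSE)
  if (test == "t" && (length(a) < 2L || length(b) < 2L)) {
    stop("the t-test needs at least two observations per group", call. = FALSE)
  }
  pooled_const <- stats::var(c(a, b)) == 0 || !is.finite(stats::var(c(a, b)))
  if (pooled_const) {
    res <- list(statistic = NA_real_, p.value = 1)
    degenerate <- TRUE
  } else {
    degenerate <- FALSE
    res <- if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(b, a, alternative = "two.sided"))
    } else {
      stats::t.test(b, a, alternative = "two.sided", var.equal = var_equal)
    }
    if (is.na(res$p.value)) {
      res$p.value <- 1
      degenerate <- TRUE
    }
  }
  data.frame(variable_id = variable_id, test = test,
             statistic = unname(res$statistic), p_value = res$p.value,
             neg_log10_p = -log10(res$p.value), degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Volcano-ready fold-change / significance table
#'
#' For every variable of a matrix (or panel), computes the log2 ratio and
#' signed fold change under each requested method, and the p-value under
#' each requested test: one tidy row per variable x method x test.
#'
#' @param x Variables-by-samples numeric matrix or a `"variable_panel"`.
#' @param labels Group labels (ignored when `x` is a panel).
#' @param methods Fold-change methods (see [fc_methods()]).
#' @param tests Character subset of `c("wilcoxon", "t")`.
#' @param p_adjust Optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`, matching the
#'   convention of reporting volcano p-values without alpha-correction.
#' @param on_error See [fold_change_matrix()]; `"na"` keeps hostile
#'   variables (e.g. non-positive values after permutation of real data)
#'   as NA records instead of aborting the scan.
#' @inheritParams fold_change.default
#' @return Data frame: `variable_id`, `method`, `log_ratio`, `fc`, `test`,
#'   `p_value`, `neg_log10_p`.
#' @export
fc_significance_table <- function(x, labels = NULL, methods = fc_methods(),
                                  tests = c("wilcoxon", "t"),
                                  bootstrap_reps = 100L, pair_cap = 1e7,
                                  seed = NULL, p_adjust = "none",
                                  on_error = c("stop", "na")) {
  if (inherits(x, "variable_panel")) {
    labels <- panel_labels(x)
    x <- as.matrix(x)
  }
  tests <- match.arg(tests, c("wilcoxon", "t"), several.ok = TRUE)
  lab <- check_labels(x, labels)
  fc_tbl <- fold_change_matrix(x, lab, methods = methods,
                               bootstrap_reps = bootstrap_reps,
                               pair_cap = pair_cap, seed = seed,
                               on_error = on_error)
  ids <- rownames(x) %||% paste0("V", seq_len(nrow(x)))
  test_tbl <- do.call(rbind, lapply(tests, function(tt) {
    tb <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
      compare_groups(x[i, lab == "reference"], x[i, lab == "treatment"],
                     test = tt, variable_id = ids[i])
    }))
    tb$p_value <- stats::p.adjust(tb$p_value, method = p_adjust)
    tb$neg_log10_p <- -log10(tb$p_value)
    tb
  }))
  out <- merge(fc_tbl, test_tbl[c("variable_id", "test", "p_value",
                                  "neg_log10_p")],
               by = "variable_id", sort = FALSE)
  out[order(match(out$variable_id, ids), out$method, out$test), ]
}

#' Spearman concordance of effect size with significance
#'
#' For every (method, test) combination in a tidy table from
#' [fc_significance_table()], the Spearman rank correlation between the
#' absolute log2 fold change and `-log10 p`, with its p-value.
#'
#' @param tbl Output of [fc_significance_table()] (needs at least three
#'   aligned variables).
#' @return Data frame: `method`, `test`, `rho`, `p_value`, `n`.
#' @export
spearman_fc_significance <- function(tbl) {
  need <- c("variable_id", "method", "log_ratio", "test", "neg_log10_p")
  if (!all(need %in% names(tbl))) {
    stop("tbl must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  combos <- unique(tbl[c("method", "test")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sub <- tbl[tbl$method == combos$method[i] & tbl$test == combos$test[i], ]
    sub <- sub[stats::complete.cases(sub[c("log_ratio", "neg_log10_p")]), ]
    if (nrow(sub) < 3L) {
      stop("need at least 3 aligned variables per method/test combination",
           call. = FALSE)
    }
    ct <- suppressWarnings(
      stats::cor.test(abs(sub$log_ratio), sub$neg_log10_p,
                      method = "spearman", exact = FALSE))
    data.frame(method = combos$method[i], test = combos$test[i],
               rho = unname(ct$estimate), p_value = ct$p.value,
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Tukey's ladder of powers
#'
#' Snap a Box-Cox exponent to the classical ladder
#' `{-2, -1, -0.5, 0, 0.5, 1, 2}` (0 denotes the log transform).  Ties
#' between two equidistant steps are broken toward 1 (no transform).
#'
#' @param lambda Numeric vector of Box-Cox exponents.
#' @return Numeric vector of ladder steps.
#' @export
snap_to_ladder <- function(lambda) {
  steps <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
  vapply(lambda, function(l) {
    if (is.na(l)) return(NA_real_)
    d <- abs(steps - l)
    cand <- steps[d == min(d)]
    cand[which.min(abs(cand - 1))]
  }, numeric(1))
}

#' Profile the distribution shape of a positive variable
#'
#' Estimates the Box-Cox exponent by profile maximum likelihood over
#' `lambda` in `[-3, 3]`, snaps it to Tukey's ladder of powers, and tests
#' normality of the raw and of the log2-transformed values with the
#' Shapiro-Wilk test at level `alpha`.  A ladder step of 0 with
#' `is_normal_logged = TRUE` is the log-normal signature; a step of 1 with
#' `is_normal_raw = TRUE` indicates data that are already close to normal.
#'
#' The Box-Cox exponent is only well identified when the spread is
#' appreciable relative to the location (coefficient of variation roughly
#' above 0.1); for nearly constant positive data far from the origin every
#' power transform is almost affine and `lambda_hat` is noisy.
#'
#' @param values Strictly positive numeric vector, length >= 8.  For
#'   samples above 5000 values the Shapiro-Wilk test is applied to 5000
#'   evenly spaced order statistics (deterministic).
#' @param alpha Normality test level (default 0.05).
#' @param lambda_grid Grid over which the profile likelihood is maximised.
#' @param variable_id Optional label.
#' @return An object of class `"dist_profile"`: list with `lambda_hat`,
#'   `ladder_step`, `is_normal_raw`, `is_normal_logged`, the two Shapiro
#'   p-values, and a `degenerate` flag (constant input).
#' @examples
#' profile_distribution(rlnorm(200, 3, 1))
#' @export
profile_distribution <- function(values, alpha = 0.05,
                                 lambda_grid = seq(-3, 3, by = 0.01),
                                 variable_id = "V1") {
  if (!is.numeric(values) || length(values) < 8L) {
    stop("values must be numeric with at least 8 observations", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values must be finite and non-missing", call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("Box-Cox profiling requires strictly positive values [variable '",
         variable_id, "']", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    return(structure(list(variable_id = variable_id, lambda_hat = NA_real_,
                          ladder_step = NA_real_, is_normal_raw = NA,
                          is_normal_logged = NA, p_raw = NA_real_,
                          p_logged = NA_real_, degenerate = TRUE),
                     class = "dist_profile"))
  }
  bc <- MASS::boxcox(values ~ 1, lambda = lambda_grid, plotit = FALSE)
  lambda_hat <- bc$x[which.max(bc$y)]
  shapiro_p <- function(x) {
    if (length(x) > 5000L) {
      x <- sort(x)[round(seq(1, length(x), length.out = 5000L))]
    }
    stats::shapiro.test(x)$p.value
  }
  p_raw <- shapiro_p(values)
  p_logged <- shapiro_p(log2(values))
  structure(list(variable_id = variable_id, lambda_hat = lambda_hat,
                 ladder_step = snap_to_ladder(lambda_hat),
                 is_normal_raw = p_raw >= alpha,
                 is_normal_logged = p_logged >= alpha,
                 p_raw = p_raw, p_logged = p_logged, degenerate = FALSE),
            class = "dist_profile")
}

#' @export
print.dist_profile <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("dist_profile '%s': degenerate (constant values)\n",
                x$variable_id))
    return(invisible(x))
  }
  cat(sprintf(
    "dist_profile '%s': lambda_hat=%.2f -> ladder %s; normal raw: %s (p=%.3g), after log2: %s (p=%.3g)\n",
    x$variable_id, x$lambda_hat,
    if (x$ladder_step == 0) "log" else format(x$ladder_step),
    x$is_normal_raw, x$p_raw, x$is_normal_logged, x$p_logged))
  invisible(x)
}

#' Normality fractions and ladder histogram of a panel
#'
#' Applies [profile_distribution()] to every variable of a matrix or panel
#' and summarises: the fraction of variables accepted as normal on the raw
#' and on the log2 scale, and the count of variables per Tukey ladder step.
#' With group labels, the same summaries are also computed within the
#' reference and the treatment group separately.
#'
#' @param x Variables-by-samples numeric matrix or `"variable_panel"`.
#' @param labels Optional group labels enabling the per-group summaries.
#' @param alpha Normality test level.
#' @param by_group Also profile the reference/treatment subsets.
#' @return List with `fractions` (data frame: `scope`, `n_variables`,
#'   `frac_normal_raw`, `frac_normal_logged`) and `ladder` (data frame of
#'   ladder-step counts per scope).  Variables failing positivity are
#'   skipped with a warning and excluded from the denominators.
#' @export
normality_fraction <- function(x, labels = NULL, alpha = 0.05,
                               by_group = !is.null(labels)) {
  if (inherits(x, "variable_panel")) {
    labels <- panel_labels(x)
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || nrow(x) < 1L) {
    stop("x must be a matrix with at least one variable", call. = FALSE)
  }
  scopes <- list(complete = seq_len(ncol(x)))
  if (by_group) {
    lab <- check_labels(x, labels)
    scopes$reference <- which(lab == "reference")
    scopes$treatment <- which(lab == "treatment")
  }
  ids <- rownames(x) %||% paste0("V", seq_len(nrow(x)))
  steps <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
  fractions <- NULL
  ladder <- NULL
  for (sc in names(scopes)) {
    profs <- lapply(seq_len(nrow(x)), function(i) {
      tryCatch(profile_distribution(x[i, scopes[[sc]]], alpha = alpha,
                                    variable_id = ids[i]),
               error = function(e) NULL)
    })
    skipped <- sum(vapply(profs, is.null, logical(1)))
    if (skipped > 0) {
      warning(sprintf("%d variable(s) not profileable in scope '%s' (non-positive or too short)",
                      skipped, sc), call. = FALSE)
    }
    profs <- Filter(function(p) !is.null(p) && !p$degenerate, profs)
    if (!length(profs)) {
      stop("no profileable variables in scope '", sc, "'", call. = FALSE)
    }
    fractions <- rbind(fractions, data.frame(
      scope = sc, n_variables = length(profs),
      frac_normal_raw = mean(vapply(profs, `[[`, logical(1), "is_normal_raw")),
      frac_normal_logged = mean(vapply(profs, `[[`, logical(1), "is_normal_logged")),
      stringsAsFactors = FALSE))
    cnt <- table(factor(vapply(profs, `[[`, numeric(1), "ladder_step"),
                        levels = steps))
    ladder <- rbind(ladder, data.frame(scope = sc, ladder_step = steps,
                                       count = as.integer(cnt),
                                       stringsAsFactors = FALSE))
  }
  list(fractions = fractions, ladder = ladder)
}
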