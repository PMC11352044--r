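#' Fold-change estimation methods
#'
#' The registry of two-group fold-change estimators supported by fcbench.
#' All of them compute a log2 ratio of treatment (`b`) over reference (`a`)
#' and differ only in the definition of the group "expected value":
#'
#' \describe{
#'   \item{`log_of_means`}{log2 of the ratio of arithmetic means,
#'     `log2(mean(b)/mean(a))`.  The method commonly treated as the default
#'     in differential-expression work, and the one most sensitive to
#'     unequal variances and skewed (log-normal) data.}
#'   \item{`log_of_medians`}{log2 of the ratio of group medians.}
#'   \item{`mean_of_logs`}{difference of the means of the log2 values, i.e.
#'     the log2 ratio of the group geometric means (alias `geometric_mean`).}
#'   \item{`median_of_logs`}{difference of the medians of the log2 values.}
#'   \item{`pairs_mean`}{mean of `log2(b_i/a_j)` over all `n_a * n_b`
#'     ordered cross pairs; algebraically identical to `mean_of_logs`.}
#'   \item{`pairs_median`}{median of `log2(b_i/a_j)` over all cross pairs
#'     (the two-sample Hodges-Lehmann estimator on the log scale).}
#'   \item{`pairs_mean_bootstrap`, `pairs_median_bootstrap`}{as above, but
#'     the pair aggregate is recomputed on groups resampled with replacement
#'     and averaged over `bootstrap_reps` replicates.}
#' }
#'
#' @return Character vector of the eight canonical method identifiers.
#' @examples
#' fc_methods()
#' @export
fc_methods <- function() {
  c("log_of_means", "log_of_medians", "mean_of_logs", "median_of_logs",
    "pairs_mean", "pairs_median", "pairs_mean_bootstrap",
    "pairs_median_bootstrap")
}

# Resolve user-supplied method names (case-insensitive, alias-aware).
match_fc_method <- function(method) {
  m <- tolower(gsub("[-. ]", "_", method))
  m[m == "geometric_mean"] <- "mean_of_logs"
  bad <- setdiff(m, fc_methods())
  if (length(bad)) {
    stop("unknown fold-change method(s): ", paste(bad, collapse = ", "),
         "; valid methods are: ",
         paste(c(fc_methods(), "geometric_mean"), collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Log2 ratio of treatment over reference by a named method
#'
#' Computes the log2 treatment/reference ratio for a single variable using
#' one estimator from [fc_methods()].  All methods operate in the log
#' domain and therefore require strictly positive measurements; violating
#' inputs raise an error naming the variable rather than being dropped.
#'
#' @param a Numeric vector of reference-group measurements (positive).
#' @param b Numeric vector of treatment-group measurements (positive).
#' @param method One method identifier (see [fc_methods()]).
#' @param bootstrap_reps Number of bootstrap replicates for the
#'   `*_bootstrap` methods (ignored otherwise).
#' @param pair_cap Maximum number of cross pairs enumerated explicitly for
#'   the `pairs_*` methods; larger pair sets are handled exactly by closed
#'   form (mean) or order-statistic selection (median).
#' @param seed Optional integer seed consulted only by the bootstrap
#'   methods; the caller's RNG state is restored afterwards.
#' @param variable_id Optional label used in error messages.
#' @return A single numeric log2 ratio.
#' @examples
#' log_ratio(c(1, 1, 1), c(3, 3, 3), "log_of_means")   # log2(3) = 1.585
#' log_ratio(c(1, 2), c(4, 8), "pairs_median")         # 2
#' @export
log_ratio <- function(a, b, method = "mean_of_logs", bootstrap_reps = 100L,
                      pair_cap = 1e7, seed = NULL, variable_id = NULL) {
  method <- match_fc_method(method)
  if (length(method) != 1L) stop("supply exactly one method", call. = FALSE)
  check_groups(a, b, variable_id, log_domain = TRUE)
  la <- log2(a)
  lb <- log2(b)
  switch(method,
    log_of_means   = log2(mean(b)) - log2(mean(a)),
    log_of_medians = log2(stats::median(b)) - log2(stats::median(a)),
    mean_of_logs   = mean(lb) - mean(la),
    median_of_logs = stats::median(lb) - stats::median(la),
    pairs_mean     = pairs_lr_mean(la, lb, pair_cap),
    pairs_median   = pairs_lr_median(la, lb, pair_cap),
    pairs_mean_bootstrap = with_seed(seed,
      pairs_lr_bootstrap(la, lb, "mean", bootstrap_reps, pair_cap)),
    pairs_median_bootstrap = with_seed(seed,
      pairs_lr_bootstrap(la, lb, "median", bootstrap_reps, pair_cap))
  )
}

#' Convert a log2 ratio to a signed symmetric fold change
#'
#' A log2 ratio `r` maps to `2^r` when `r >= 0` and to `-2^(-r)` otherwise,
#' so up- and down-regulation are symmetric around +/-1: a third-fold change
#' is reported as -3, not 0.33.  `log_ratio_from_fc()` is the inverse.
#'
#' @param log_ratio Numeric vector of log2 ratios (finite).
#' @return Numeric vector of signed fold changes with `|fc| >= 1`.
#' @examples
#' fc_from_log_ratio(c(0, 1.58496, -1.58496))  # 1, 3, -3
#' @export
fc_from_log_ratio <- function(log_ratio) {
  if (!is.numeric(log_ratio) || anyNA(log_ratio) || any(!is.finite(log_ratio))) {
    stop("log_ratio must be finite numeric", call. = FALSE)
  }
  ifelse(log_ratio >= 0, 2^log_ratio, -(2^(-log_ratio)))
}

#' @rdname fc_from_log_ratio
#' @param fc Numeric vector of signed fold changes (`|fc| >= 1`) or plain
#'   positive ratios.
#' @export
log_ratio_from_fc <- function(fc) {
  if (!is.numeric(fc) || anyNA(fc) || any(!is.finite(fc)) || any(fc == 0)) {
    stop("fc must be finite non-zero numeric", call. = FALSE)
  }
  if (any(fc < 0 & fc > -1)) {
    stop("a signed fold change cannot lie in (-1, 0)", call. = FALSE)
  }
  out <- fc
  out[fc > 0] <- log2(fc[fc > 0])
  out[fc < 0] <- -log2(-fc[fc < 0])
  out
}

# Map a positive ratio (or an already-signed fold) onto the signed
# symmetric fold scale: r >= 1 -> r, 0 < r < 1 -> -1/r.
signed_fold <- function(x, what = "fold change") {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be finite numeric", call. = FALSE)
  }
  if (any(x <= 0 & x > -1)) {
    stop(what, " must be a positive ratio or a signed fold with |x| >= 1",
         call. = FALSE)
  }
  out <- x
  pos <- x > 0
  lr <- log2(x[pos])
  out[pos] <- sign(lr) * 2^abs(lr)
  out[x > 0 & x == 1] <- 1
  out
}

#' Signed fold-change recovery error
#'
#' Error of a calculated fold change against the true one, measured on the
#' signed symmetric fold scale:
#' `sign(log2 FCcalc) * 2^|log2 FCcalc| - sign(log2 FCtrue) * 2^|log2 FCtrue|`.
#' Inputs may be positive ratios (`1/3` is treated as `-3`) or already-signed
#' folds.  The result is 0 on perfect recovery and antisymmetric in its
#' arguments.
#'
#' @param fc_calculated,fc_true Positive ratios or signed folds (vectorised).
#' @return Numeric vector of signed errors in fold units.
#' @examples
#' error_fc(2, 3)      # -1
#' error_fc(0.5, 2)    # -4  ( -2 - (+2) )
#' @export
error_fc <- function(fc_calculated, fc_true) {
  signed_fold(fc_calculated, "fc_calculated") - signed_fold(fc_true, "fc_true")
}

#' Estimate a fold change by one or several methods
#'
#' The central fitting function: given reference measurements `a` and
#' treatment measurements `b` of one variable, estimates the log2 ratio and
#' signed fold change under each requested method and returns a classed
#' object with the usual `print()`, `summary()` and `coef()` methods.
#'
#' @param a Reference-group measurements (positive numeric), a
#'   [grouped_sample()], or a formula `value ~ group`.
#' @param ... Passed on between methods.
#' @export
fold_change <- function(a, ...) UseMethod("fold_change")

#' @rdname fold_change
#' @inheritParams log_ratio
#' @param methods Character vector of method identifiers (default: all
#'   eight from [fc_methods()]).
#' @param fc_true Optional known true ratio; when supplied, the per-method
#'   [error_fc()] is included in the results table.
#' @return An object of class `"fold_change"`: a list with a `results`
#'   data frame (`variable_id`, `method`, `log_ratio`, `fc`, and `error`
#'   when `fc_true` is known), the group data and the call.
#' @examples
#' fit <- fold_change(c(1, 2), c(4, 8))
#' coef(fit)
#' @export
fold_change.default <- function(a, b, methods = fc_methods(),
                                bootstrap_reps = 100L, pair_cap = 1e7,
                                seed = NULL, variable_id = "V1",
                                fc_true = NULL, ...) {
  methods <- match_fc_method(methods)
  check_groups(a, b, variable_id, log_domain = TRUE)
  seeds <- derive_seeds(seed, length(methods))
  lr <- vapply(seq_along(methods), function(i) {
    log_ratio(a, b, methods[i], bootstrap_reps = bootstrap_reps,
              pair_cap = pair_cap, seed = seeds[i], variable_id = variable_id)
  }, numeric(1))
  res <- data.frame(variable_id = variable_id, method = methods,
                    log_ratio = lr, fc = fc_from_log_ratio(lr),
                    stringsAsFactors = FALSE)
  if (!is.null(fc_true)) res$error <- error_fc(res$fc, fc_true)
  structure(list(results = res, a = a, b = b, fc_true = fc_true,
                 seed = seed, call = match.call()),
            class = "fold_change")
}

#' @rdname fold_change
#' @param data Data frame holding the variables of a formula interface.
#' @param reference Group label to treat as the reference level; defaults
#'   to the first factor level of the grouping variable.
#' @export
fold_change.formula <- function(a, data = NULL, reference = NULL, ...) {
  mf <- stats::model.frame(a, data = data)
  if (ncol(mf) != 2L) stop("formula must be of the form value ~ group", call. = FALSE)
  y <- mf[[1L]]
  g <- as.factor(mf[[2L]])
  if (nlevels(g) != 2L) stop("grouping variable must have exactly two levels", call. = FALSE)
  reference <- reference %||% levels(g)[1L]
  if (!reference %in% levels(g)) {
    stop("reference level '", reference, "' not found in grouping variable",
         call. = FALSE)
  }
  fold_change.default(a = y[g == reference], b = y[g != reference], ...)
}

#' @rdname fold_change
#' @export
fold_change.grouped_sample <- function(a, ...) {
  dots <- list(...)
  if (is.null(dots$fc_true)) dots$fc_true <- a$fc_true
  do.call(fold_change.default,
          c(list(a = a$a, b = a$b, variable_id = a$variable_id), dots))
}

#' @export
print.fold_change <- function(x, digits = 4, ...) {
  cat("Two-group fold-change estimates (treatment b vs reference a)\n")
  cat(sprintf("  n_a = %d, n_b = %d\n", length(x$a), length(x$b)))
  if (!is.null(x$fc_true)) {
    cat(sprintf("  true ratio = %s (signed fold %s)\n",
                format(x$fc_true, digits = digits),
                format(signed_fold(x$fc_true), digits = digits)))
  }
  print(format_df_num(x$results, digits), row.names = FALSE)
  invisible(x)
}

#' @export
summary.fold_change <- function(object, ...) {
  structure(list(fit = object,
                 group_summary = rbind(a = summary(object$a),
                                       b = summary(object$b)),
                 spread = c(range = diff(range(object$results$log_ratio)),
                            sd = stats::sd(object$results$log_ratio))),
            class = "summary.fold_change")
}

#' @export
print.summary.fold_change <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nGroup summaries:\n")
  print(x$group_summary, digits = digits)
  cat(sprintf("\nBetween-method spread of log2 ratios: range %.4g, sd %.4g\n",
              x$spread[["range"]], x$spread[["sd"]]))
  cat("Large spread indicates method-sensitive (skewed or unequal-variance) data.\n")
  invisible(x)
}

#' @export
coef.fold_change <- function(object, type = c("log_ratio", "fc"), ...) {
  type <- match.arg(type)
  stats::setNames(object$results[[type]], object$results$method)
}

#' Fold changes for every variable of a matrix
#'
#' Applies [fold_change()] row-wise to a variables-by-samples matrix with a
#' two-group sample labelling and returns a tidy table.
#'
#' @param x Numeric matrix, variables as rows, samples as columns.
#' @param labels Character/factor vector of length `ncol(x)` with values
#'   `"reference"` and `"treatment"` (or a named vector keyed by column
#'   name).
#' @inheritParams fold_change.default
#' @param on_error `"stop"` surfaces the first per-variable domain error
#'   (e.g. non-positive measurements) naming the variable; `"na"` turns
#'   such variables into NA records with a warning, so large scans of
#'   hostile data keep going.
#' @return Data frame with one row per variable x method: `variable_id`,
#'   `method`, `log_ratio`, `fc`.
#' @export
fold_change_matrix <- function(x, labels, methods = fc_methods(),
                               bootstrap_reps = 100L, pair_cap = 1e7,
                               seed = NULL, on_error = c("stop", "na")) {
  lab <- check_labels(x, labels)
  on_error <- match.arg(on_error)
  methods <- match_fc_method(methods)
  ids <- rownames(x) %||% paste0("V", seq_len(nrow(x)))
  seeds <- derive_seeds(seed, nrow(x))
  n_failed <- 0L
  out <- lapply(seq_len(nrow(x)), function(i) {
    res <- tryCatch(
      fold_change.default(
        a = x[i, lab == "reference"], b = x[i, lab == "treatment"],
        methods = methods, bootstrap_reps = bootstrap_reps,
        pair_cap = pair_cap, seed = seeds[i], variable_id = ids[i])$results,
      error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "stop") stop(res)
      n_failed <<- n_failed + 1L
      res <- data.frame(variable_id = ids[i], method = methods,
                        log_ratio = NA_real_, fc = NA_real_,
                        stringsAsFactors = FALSE)
    }
    res
  })
  if (n_failed > 0L) {
    warning(sprintf("%d variable(s) not estimable (see on_error); recorded as NA",
                    n_failed), call. = FALSE)
  }
  do.call(rbind, out)
}

# Validate a label vector against a matrix; returns labels aligned to columns.
check_labels <- function(x, labels) {
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix", call. = FALSE)
  if (!is.null(names(labels)) && !is.null(colnames(x))) {
    missing_ids <- setdiff(colnames(x), names(labels))
    if (length(missing_ids)) {
      stop("samples missing from labels: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[colnames(x)]
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) {
    stop("labels must cover every sample column", call. = FALSE)
  }
  bad <- setdiff(unique(labels), c("reference", "treatment"))
  if (length(bad)) {
    stop("labels must be 'reference' or 'treatment'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both a reference and a treatment group are required", call. = FALSE)
  }
  labels
}

# pretty-print helper: round numeric columns for display only
format_df_num <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  df
}
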