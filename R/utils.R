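# Internal helpers: seeded evaluation and input validation.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL means "use the current RNG stream" (no restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Draw n child seeds (31-bit, suitable for set.seed) from a master seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# Validate one two-group sample; log_domain adds strict positivity.
check_groups <- function(a, b, variable_id = NULL, log_domain = TRUE) {
  tag <- if (is.null(variable_id)) "" else sprintf(" [variable '%s']", variable_id)
  if (length(a) < 1L || length(b) < 1L) {
    stop("both groups need at least one observation", tag, call. = FALSE)
  }
  if (!is.numeric(a) || !is.numeric(b)) {
    stop("group measurements must be numeric", tag, call. = FALSE)
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("group measurements must be finite and non-missing", tag, call. = FALSE)
  }
  if (log_domain && (any(a <= 0) || any(b <= 0))) {
    stop("log-domain fold-change methods require strictly positive values; ",
         "found non-positive measurements", tag,
         " (no pseudo-count is applied)", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
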