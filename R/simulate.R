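#' Specification of one synthetic two-group variable
#'
#' Describes how to draw one variable's reference vector `a` and treatment
#' vector `b` with a known true ratio `fc_true`.  Families:
#'
#' \describe{
#'   \item{`identity`}{`a` is `n_a` copies of `m_a`; `b` is `n_b` copies of
#'     `fc_true * m_a` (deterministic).}
#'   \item{`uniform`}{`a = U(0,1) * m_a`; `b = U(0,1) * m_a * fc_true`
#'     (independent uniform streams).}
#'   \item{`normal`}{`a ~ N(m_a, s_a)`, `b ~ N(fc_true * m_a, s_b)` with
#'     `s_*` in measurement units.}
#'   \item{`lognormal`}{`a ~ LogNormal(log m_a, s_a)`,
#'     `b ~ LogNormal(log fc_true + log m_a, s_b)` with natural-log location
#'     and `s_*` on the natural-log scale, so `fc_true` is the ratio of the
#'     group medians (and geometric means), not of the arithmetic means.}
#'   \item{`mixed_normal_lognormal`}{`a` normal, `b` log-normal (as above).}
#'   \item{`mixed_lognormal_normal`}{`a` log-normal, `b` normal.}
#'   \item{`mixed`}{each element of each group drawn from one of the four
#'     base families chosen uniformly at random per element.}
#' }
#'
#' @param family Distribution family (see Details).
#' @param m_a Location of the reference group (positive).
#' @param fc_true True treatment/reference ratio (positive).
#' @param s_a,s_b Spread of the reference / treatment group: a standard
#'   deviation in measurement units for `normal`, on the natural-log scale
#'   for `lognormal`; ignored by `identity` and `uniform`.
#' @param n_a,n_b Group sizes (>= 1).
#' @param seed Optional integer seed making the draw reproducible.
#' @param variable_id Label attached to the generated sample.
#' @return An object of class `"sim_spec"`.
#' @examples
#' sim_spec("lognormal", m_a = 35, fc_true = 2, s_a = 1, s_b = 1, n_a = 100, n_b = 100)
#' @export
sim_spec <- function(family = c("identity", "uniform", "normal", "lognormal",
                                "mixed_normal_lognormal",
                                "mixed_lognormal_normal", "mixed"),
                     m_a = 100, fc_true = 1, s_a = 0, s_b = 0,
                     n_a = 10L, n_b = 10L, seed = NULL, variable_id = "V1") {
  family <- match.arg(family)
  stopifnot(is.numeric(m_a), length(m_a) == 1L, m_a > 0,
            is.numeric(fc_true), length(fc_true) == 1L, fc_true > 0,
            is.numeric(s_a), s_a >= 0, is.numeric(s_b), s_b >= 0,
            n_a >= 1L, n_b >= 1L)
  structure(list(family = family, m_a = m_a, fc_true = fc_true,
                 s_a = s_a, s_b = s_b, n_a = as.integer(n_a),
                 n_b = as.integer(n_b), seed = seed,
                 variable_id = variable_id),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "sim_spec: %s  m_a=%g  fc_true=%g  s_a=%g  s_b=%g  n_a=%d  n_b=%d  seed=%s\n",
    x$family, x$m_a, x$fc_true, x$s_a, x$s_b, x$n_a, x$n_b,
    x$seed %||% "NULL"))
  invisible(x)
}

#' Construct a two-group sample
#'
#' Container for one variable's reference (`a`) and treatment (`b`)
#' measurements, optionally tagged with the true ratio used to generate it.
#' Non-positive values are permitted at construction (a `normal` draw can
#' produce them); they are flagged via `contains_nonpositive` and rejected
#' later by the log-domain estimators.
#'
#' @param a,b Numeric measurement vectors (length >= 1, finite).
#' @param variable_id Opaque label.
#' @param fc_true Optional known true ratio.
#' @param spec Optional generating [sim_spec()].
#' @return An object of class `"grouped_sample"`.
#' @export
grouped_sample <- function(a, b, variable_id = "V1", fc_true = NULL,
                           spec = NULL) {
  check_groups(a, b, variable_id, log_domain = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 variable_id = variable_id, fc_true = fc_true, spec = spec,
                 contains_nonpositive = any(a <= 0) || any(b <= 0)),
            class = "grouped_sample")
}

#' @export
print.grouped_sample <- function(x, ...) {
  cat(sprintf("grouped_sample '%s': n_a=%d, n_b=%d%s%s\n", x$variable_id,
              length(x$a), length(x$b),
              if (!is.null(x$fc_true)) sprintf(", fc_true=%g", x$fc_true) else "",
              if (x$contains_nonpositive) " [contains non-positive values]" else ""))
  invisible(x)
}

# one group from one base family
draw_group <- function(family, n, m, s) {
  switch(family,
    identity  = rep(m, n),
    uniform   = stats::runif(n) * m,
    normal    = stats::rnorm(n, m, s),
    lognormal = stats::rlnorm(n, log(m), s))
}

# per-element mixture of the four base families
draw_mixed <- function(n, m, s) {
  fam <- sample(c("identity", "uniform", "normal", "lognormal"), n,
                replace = TRUE)
  out <- numeric(n)
  for (f in unique(fam)) {
    idx <- which(fam == f)
    out[idx] <- draw_group(f, length(idx), m, s)
  }
  out
}

#' Generate a two-group sample from a simulation specification
#'
#' @param spec A [sim_spec()].
#' @return A [grouped_sample()] with `fc_true` attached; regenerating with
#'   the same spec (including seed) is bit-identical.
#' @examples
#' s <- generate_sample(sim_spec("identity", m_a = 10, fc_true = 3, n_a = 5, n_b = 5))
#' s$a; s$b
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  m_b <- spec$fc_true * spec$m_a
  ab <- with_seed(spec$seed, {
    a <- switch(spec$family,
      identity  = draw_group("identity", spec$n_a, spec$m_a, spec$s_a),
      uniform   = draw_group("uniform", spec$n_a, spec$m_a, spec$s_a),
      normal    = draw_group("normal", spec$n_a, spec$m_a, spec$s_a),
      lognormal = draw_group("lognormal", spec$n_a, spec$m_a, spec$s_a),
      mixed_normal_lognormal = draw_group("normal", spec$n_a, spec$m_a, spec$s_a),
      mixed_lognormal_normal = draw_group("lognormal", spec$n_a, spec$m_a, spec$s_a),
      mixed = draw_mixed(spec$n_a, spec$m_a, spec$s_a))
    b <- switch(spec$family,
      identity  = draw_group("identity", spec$n_b, m_b, spec$s_b),
      uniform   = draw_group("uniform", spec$n_b, m_b, spec$s_b),
      normal    = draw_group("normal", spec$n_b, m_b, spec$s_b),
      lognormal = draw_group("lognormal", spec$n_b, m_b, spec$s_b),
      mixed_normal_lognormal = draw_group("lognormal", spec$n_b, m_b, spec$s_b),
      mixed_lognormal_normal = draw_group("normal", spec$n_b, m_b, spec$s_b),
      mixed = draw_mixed(spec$n_b, m_b, spec$s_b))
    list(a = a, b = b)
  })
  grouped_sample(ab$a, ab$b, variable_id = spec$variable_id,
                 fc_true = spec$fc_true, spec = spec)
}

#' Log-normal sweep over fold change and variance ratio
#'
#' Generates one log-normal two-group sample per cell of the Cartesian grid
#' `fc_grid x s_ratio_grid x s_a_levels` with `s_b = s_ratio * s_a`.  The
#' default grids are a 20-point fold-change grid spanning 0.1 to 6, variance
#' ratios 0.1, 0.5, 1, 2, 4, 8 and reference spreads 0.1 and 1 (natural-log
#' scale).
#'
#' @param fc_grid Positive numeric grid of true ratios.
#' @param s_ratio_grid Positive grid of `s_b / s_a` ratios.
#' @param s_a_levels Reference-group spread levels (natural-log scale).
#' @param n Group size for both groups.
#' @param m_a Reference location.
#' @param seed Optional master seed; per-cell seeds are derived from it.
#' @return An object of class `"fc_sweep"`: list with `grid` (data frame of
#'   cell parameters and per-cell seeds) and `samples` (list of
#'   [grouped_sample()]s aligned with the grid rows).
#' @export
generate_sweep <- function(fc_grid = seq(0.1, 6, length.out = 20),
                           s_ratio_grid = c(0.1, 0.5, 1, 2, 4, 8),
                           s_a_levels = c(0.1, 1),
                           n = 10000L, m_a = 100, seed = NULL) {
  if (!length(fc_grid) || !length(s_ratio_grid) || !length(s_a_levels)) {
    stop("all grids must be non-empty", call. = FALSE)
  }
  if (any(fc_grid <= 0)) stop("fc_grid must be strictly positive", call. = FALSE)
  grid <- expand.grid(fc_true = fc_grid, s_ratio = s_ratio_grid,
                      s_a = s_a_levels, KEEP.OUT.ATTRS = FALSE)
  grid$s_b <- grid$s_ratio * grid$s_a
  grid$seed <- derive_seeds(seed, nrow(grid))
  samples <- lapply(seq_len(nrow(grid)), function(i) {
    generate_sample(sim_spec("lognormal", m_a = m_a,
                             fc_true = grid$fc_true[i], s_a = grid$s_a[i],
                             s_b = grid$s_b[i], n_a = n, n_b = n,
                             seed = grid$seed[i],
                             variable_id = sprintf("cell%04d", i)))
  })
  structure(list(grid = grid, samples = samples, n = as.integer(n),
                 m_a = m_a, seed = seed),
            class = "fc_sweep")
}

#' Specification of a multi-variable synthetic panel
#'
#' Describes a panel of `d` independent two-group variables with per-variable
#' parameters drawn from predefined ranges: true ratios uniform on
#' `ratio_range`; for log-normal variables a location `m ~ U(30, 40)` and
#' log-scale spreads `s_a, s_b ~ U(1, 5)`; for normal variables
#' `m ~ U(500, 600)` and `s_a, s_b ~ U(20, 200)` in measurement units.
#'
#' @param d Number of variables.
#' @param family `"normal"`, `"lognormal"`, `"mixed"` (per-variable random
#'   pick between the two), or a length-`d` vector of families.
#' @param ratio_range Interval for `fc_true` (default `c(1/3, 3)`).
#' @param lognormal_m_range,lognormal_s_range,normal_m_range,normal_s_range
#'   Parameter-draw ranges per family.
#' @param n_a,n_b Group sizes.
#' @param seed Optional master seed.
#' @return An object of class `"panel_spec"`.
#' @export
panel_spec <- function(d = 99L, family = "lognormal",
                       ratio_range = c(1/3, 3),
                       lognormal_m_range = c(30, 40),
                       lognormal_s_range = c(1, 5),
                       normal_m_range = c(500, 600),
                       normal_s_range = c(20, 200),
                       n_a = 50L, n_b = 50L, seed = NULL) {
  stopifnot(d >= 1L, length(ratio_range) == 2L, all(ratio_range > 0),
            diff(ratio_range) >= 0, n_a >= 1L, n_b >= 1L)
  if (!(length(family) %in% c(1L, d))) {
    stop("family must be length 1 or d", call. = FALSE)
  }
  ok <- c("normal", "lognormal", "mixed")
  if (!all(family %in% ok)) {
    stop("family must be one of: ", paste(ok, collapse = ", "), call. = FALSE)
  }
  structure(list(d = as.integer(d), family = family,
                 ratio_range = ratio_range,
                 lognormal_m_range = lognormal_m_range,
                 lognormal_s_range = lognormal_s_range,
                 normal_m_range = normal_m_range,
                 normal_s_range = normal_s_range,
                 n_a = as.integer(n_a), n_b = as.integer(n_b), seed = seed),
            class = "panel_spec")
}

runif_range <- function(n, range) {
  if (diff(range) == 0) rep(range[1], n) else stats::runif(n, range[1], range[2])
}

#' Generate a multi-variable panel with known true fold changes
#'
#' @param spec A [panel_spec()].
#' @return An object of class `"variable_panel"`: list with `samples` (list
#'   of [grouped_sample()]s), `meta` (data frame of drawn per-variable
#'   parameters incl. `fc_true` and per-variable seeds), group sizes, and
#'   the spec.  Convertible to matrix form with [as.matrix()] /
#'   [panel_labels()].
#' @examples
#' p <- generate_panel(panel_spec(d = 5, family = "normal", seed = 1))
#' p$meta
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  d <- spec$d
  master <- derive_seeds(spec$seed, d + 1L)
  meta <- with_seed(master[1L], {
    fam <- if (length(spec$family) == d) spec$family else rep(spec$family, d)
    fam[fam == "mixed"] <- sample(c("normal", "lognormal"),
                                  sum(fam == "mixed"), replace = TRUE)
    data.frame(
      variable_id = sprintf("V%03d", seq_len(d)),
      family = fam,
      fc_true = runif_range(d, spec$ratio_range),
      m = ifelse(fam == "lognormal",
                 runif_range(d, spec$lognormal_m_range),
                 runif_range(d, spec$normal_m_range)),
      s_a = ifelse(fam == "lognormal",
                   runif_range(d, spec$lognormal_s_range),
                   runif_range(d, spec$normal_s_range)),
      s_b = ifelse(fam == "lognormal",
                   runif_range(d, spec$lognormal_s_range),
                   runif_range(d, spec$normal_s_range)),
      stringsAsFactors = FALSE)
  })
  meta$seed <- master[-1L]
  samples <- lapply(seq_len(d), function(i) {
    generate_sample(sim_spec(meta$family[i], m_a = meta$m[i],
                             fc_true = meta$fc_true[i], s_a = meta$s_a[i],
                             s_b = meta$s_b[i], n_a = spec$n_a,
                             n_b = spec$n_b, seed = meta$seed[i],
                             variable_id = meta$variable_id[i]))
  })
  structure(list(samples = samples, meta = meta, n_a = spec$n_a,
                 n_b = spec$n_b, spec = spec),
            class = "variable_panel")
}

#' @export
print.variable_panel <- function(x, ...) {
  cat(sprintf("variable_panel: d=%d variables, n_a=%d, n_b=%d\n",
              nrow(x$meta), x$n_a, x$n_b))
  cat("families:", paste(sprintf("%s (%d)", names(table(x$meta$family)),
                                 table(x$meta$family)), collapse = ", "), "\n")
  invisible(x)
}

#' Matrix form of a panel
#'
#' `as.matrix()` lays a panel out as a variables-by-samples numeric matrix
#' (reference columns first); `panel_labels()` returns the matching named
#' group-label vector (`"reference"` / `"treatment"` keyed by sample id).
#'
#' @param x A `"variable_panel"`.
#' @param ... Unused.
#' @return Numeric matrix `d x (n_a + n_b)` with variable ids as row names
#'   and sample ids as column names.
#' @export
as.matrix.variable_panel <- function(x, ...) {
  m <- t(vapply(x$samples, function(s) c(s$a, s$b),
                numeric(x$n_a + x$n_b)))
  rownames(m) <- x$meta$variable_id
  colnames(m) <- c(sprintf("ref_%03d", seq_len(x$n_a)),
                   sprintf("trt_%03d", seq_len(x$n_b)))
  m
}

#' @rdname as.matrix.variable_panel
#' @param panel A `"variable_panel"`.
#' @export
panel_labels <- function(panel) {
  stopifnot(inherits(panel, "variable_panel"))
  stats::setNames(rep(c("reference", "treatment"), c(panel$n_a, panel$n_b)),
                  c(sprintf("ref_%03d", seq_len(panel$n_a)),
                    sprintf("trt_%03d", seq_len(panel$n_b))))
}

#' Globally permute a data matrix
#'
#' Shuffles all matrix entries across both dimensions (flatten, seeded
#' shuffle, reshape).  This destroys the variable/sample structure while
#' preserving the multiset of values -- and hence all pooled moments -- and
#' the group-size split.  Used to stress-test how fold-change estimators and
#' tests behave when per-variable distributions become arbitrary mixtures of
#' the whole matrix.
#'
#' @param x Numeric matrix (non-empty).
#' @param seed Optional integer seed.
#' @return Matrix of the same shape and dimnames with entries permuted.
#' @export
permute_matrix <- function(x, seed = NULL) {
  if (!is.matrix(x) || length(x) == 0L) {
    stop("x must be a non-empty matrix", call. = FALSE)
  }
  v <- as.vector(x)
  out <- with_seed(seed, matrix(v[sample.int(length(v))], nrow = nrow(x)))
  dimnames(out) <- dimnames(x)
  out
}
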