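# Plain-text I/O: delimited matrices, label files, panel serialisation,
# experiment exports and run configurations.

#' Read an expression matrix with two-group sample labels
#'
#' Reads a delimited variables-by-samples matrix (header row = sample ids,
#' first column = variable ids) together with a two-column label file
#' mapping every sample id to `reference` or `treatment`.
#'
#' @param path Matrix file (TSV by default; use `sep = ","` for CSV).
#' @param labels_path Two-column label file (`sample_id`, `group`); a
#'   header line is detected automatically.
#' @param sep Field separator for both files.
#' @param transpose Set when the file stores samples as rows.
#' @return List with `matrix` (numeric, variables x samples) and `labels`
#'   (named character vector aligned to the columns).
#' @export
read_matrix <- function(path, labels_path, sep = "\t", transpose = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("matrix file must have id column plus data", call. = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate variable ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(raw[-1L])
  if (!is.numeric(m)) {
    bad <- colnames(m)[!vapply(raw[-1L], is.numeric, logical(1))]
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  lab_raw <- utils::read.table(labels_path, header = FALSE, sep = sep,
                               stringsAsFactors = FALSE)
  if (ncol(lab_raw) != 2L) {
    stop("labels file must have exactly two columns (sample_id, group)",
         call. = FALSE)
  }
  if (tolower(lab_raw[1, 2]) %in% c("group", "label", "condition")) {
    lab_raw <- lab_raw[-1L, , drop = FALSE]
  }
  labels <- stats::setNames(tolower(lab_raw[[2L]]), lab_raw[[1L]])
  labels <- check_labels_named(m, labels)
  list(matrix = m, labels = labels)
}

check_labels_named <- function(m, labels) {
  missing_ids <- setdiff(colnames(m), names(labels))
  if (length(missing_ids)) {
    stop("samples missing from labels: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  labels <- labels[colnames(m)]
  check_labels(m, labels)
  labels
}

#' Write a synthetic panel to plain-text files
#'
#' Serialises a [generate_panel()] result as three files under `dir`:
#' `<name>_matrix.tsv` (variables x samples, header = sample ids, first
#' column = variable ids), `<name>_labels.tsv` (sample_id, group), and a
#' sidecar `<name>_specs.json` recording every per-variable generating
#' parameter including `fc_true` and seed.
#'
#' @param panel A `"variable_panel"`.
#' @param dir Output directory (created if absent).
#' @param name File basename.
#' @return Invisibly, the three file paths.
#' @export
write_panel <- function(panel, dir, name = "panel") {
  stopifnot(inherits(panel, "variable_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- as.matrix(panel)
  paths <- file.path(dir, paste0(name, c("_matrix.tsv", "_labels.tsv",
                                         "_specs.json")))
  fm <- matrix(sprintf("%.17g", m), nrow = nrow(m), dimnames = dimnames(m))
  df <- data.frame(variable_id = rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- panel_labels(panel)
  utils::write.table(data.frame(sample_id = names(lab), group = unname(lab)),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_a = panel$n_a, n_b = panel$n_b,
         variables = panel$meta),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Export an experiment to TSV tables and a JSON manifest
#'
#' Writes the tidy cell table and every auxiliary table of an
#' `"fc_experiment"` as TSV (full double precision), plus a JSON manifest
#' recording the experiment id, all parameters and seeds, and software
#' versions.  Optionally also renders the experiment's default plot to PNG.
#'
#' @param x An `"fc_experiment"`.
#' @param dir Output directory (created if absent).
#' @param name File basename (default: the experiment id).
#' @param plots Also write `<name>.png` via [plot.fc_experiment()].
#' @return Invisibly, the written paths.
#' @export
write_experiment <- function(x, dir, name = x$experiment_id, plots = FALSE) {
  stopifnot(inherits(x, "fc_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  tables <- Filter(is.data.frame, x[setdiff(names(x),
                                            c("experiment_id", "params"))])
  for (nm in names(tables)) {
    p <- file.path(dir, sprintf("%s_%s.tsv", name, nm))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(experiment_id = x$experiment_id, params = x$params,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   r_version = R.version.string,
                   package = "fcbench",
                   package_version = as.character(utils::packageVersion("fcbench")))
  mp <- file.path(dir, sprintf("%s_manifest.json", name))
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, mp)
  if (plots) {
    pp <- file.path(dir, paste0(name, ".png"))
    grDevices::png(pp, width = 1200, height = 800, res = 120)
    on.exit(grDevices::dev.off())
    plot(x)
    paths <- c(paths, pp)
  }
  invisible(paths)
}

#' Run configuration
#'
#' A serialisable bag of generator / method / test parameters with the
#' package defaults filled in.  `write_config()` and `read_config()`
#' round-trip it through YAML or JSON (chosen by file extension).
#'
#' @param experiment One of the experiment identifiers.
#' @param ... Overrides for any default field.
#' @return A named list of class `"fc_config"`.
#' @export
fc_config <- function(experiment = c("distribution_stress", "variance_sweep",
                                     "significance_panel",
                                     "permutation_stress"), ...) {
  experiment <- match.arg(experiment)
  cfg <- list(
    experiment = experiment,
    seed = NULL,
    out = ".",
    methods = fc_methods(),
    tests = c("wilcoxon", "t"),
    bootstrap_reps = 100L,
    pair_cap = 1e7,
    n_levels = c(10L, 10000L),
    reps = 25L,
    fc_true = 2,
    m_a = 100,
    s_normal = 10,
    s_lognormal = 1,
    fc_grid = seq(0.1, 6, length.out = 20),
    s_ratio_grid = c(0.1, 0.5, 1, 2, 4, 8),
    s_a_levels = c(0.1, 1),
    n = 10000L,
    d = 99L,
    families = c("normal", "lognormal"),
    n_a = 50L,
    n_b = 50L,
    plots = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "fc_config")
}

#' @rdname fc_config
#' @param cfg An `"fc_config"`.
#' @param path Destination (`.yaml`/`.yml` or `.json`).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fc_config") || is.list(cfg))
  ext <- tolower(tools::file_ext(path))
  plain <- unclass(cfg)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' @rdname fc_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  }
  base <- fc_config(raw$experiment %||% "distribution_stress")
  for (nm in setdiff(names(raw), "experiment")) {
    if (!is.null(raw[[nm]])) {
      tmpl <- base[[nm]]
      base[[nm]] <- if (is.numeric(tmpl) && !is.null(raw[[nm]])) {
        v <- as.numeric(raw[[nm]])
        if (is.integer(tmpl)) as.integer(v) else v
      } else raw[[nm]]
    }
  }
  base
}

#' Write a tidy fold-change table at full precision
#'
#' Numeric columns are serialised with 17 significant digits, which
#' round-trips IEEE doubles exactly.
#'
#' @param tbl Data frame (e.g. from [fc_significance_table()]).
#' @param path Destination TSV.
#' @export
write_fc_table <- function(tbl, path) {
  num <- vapply(tbl, is.double, logical(1))
  tbl[num] <- lapply(tbl[num], function(v) sprintf("%.17g", v))
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
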