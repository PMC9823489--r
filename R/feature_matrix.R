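#' Construct a labelled feature matrix
#'
#' The container every other function in the package operates on: a numeric
#' samples-by-features matrix plus a categorical label per sample. Column
#' order is significant — agents are positional, so feature index `i` always
#' means the `i`-th column as loaded.
#'
#' @param values Numeric matrix, `n_samples x n_features`.
#' @param labels Vector of class identifiers, one per sample (coerced to
#'   factor).
#' @param feature_names Optional character vector of unique feature names;
#'   defaults to the column names of `values`, or `f1..fN`.
#' @return An object of class `feature_matrix` with elements `values`
#'   (matrix), `labels` (factor), `feature_names` (character) and
#'   `n_features`.
#' @export
feature_matrix <- function(values, labels, feature_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("feature values must be numeric", call. = FALSE)
  }
  if (nrow(values) < 2L) {
    stop("a feature matrix needs at least 2 samples", call. = FALSE)
  }
  if (ncol(values) < 1L) {
    stop("a feature matrix needs at least 1 feature", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("feature values contain missing entries", call. = FALSE)
  }
  if (length(labels) != nrow(values)) {
    stop("labels must have one entry per sample", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) {
      feature_names <- paste0("f", seq_len(ncol(values)))
    }
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(values)) {
    stop("feature_names must have one entry per feature", call. = FALSE)
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique", call. = FALSE)
  }
  colnames(values) <- feature_names
  structure(
    list(
      values = values,
      labels = factor(labels),
      feature_names = feature_names,
      n_features = ncol(values)
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d samples x %d features, %d classes (%s)\n",
    nrow(x$values), x$n_features, nlevels(x$labels),
    paste(utils::head(levels(x$labels), 5), collapse = ", ")
  ))
  invisible(x)
}

n_samples <- function(data) nrow(data$values)

# At least two classes are required before any training run.
check_trainable <- function(data) {
  if (nlevels(droplevels(data$labels)) < 2L) {
    stop("labels must contain at least 2 distinct classes", call. = FALSE)
  }
  invisible(data)
}

#' Load a labelled feature table from delimited text
#'
#' Reads a CSV/TSV file with a header row, one designated label column, and
#' numeric feature columns. Column order in the file becomes feature index
#' order.
#'
#' @param path Path to the delimited file.
#' @param label_column Name of the label column (required).
#' @param delimiter Field delimiter; `","` by default, use `"\t"` for TSV.
#' @param drop_columns Optional character vector of columns to discard
#'   before parsing (e.g. identifier columns).
#' @param impute If `TRUE`, missing feature cells are replaced by the column
#'   mean; by default missing values are an error.
#' @return A [feature_matrix()].
#' @export
load_table <- function(path, label_column, delimiter = ",",
                       drop_columns = NULL, impute = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found in %s", label_column, path),
         call. = FALSE)
  }
  if (!is.null(drop_columns)) {
    missing_cols <- setdiff(drop_columns, names(df))
    if (length(missing_cols)) {
      stop(sprintf("drop_columns not present: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    df <- df[, setdiff(names(df), drop_columns), drop = FALSE]
  }
  labels <- df[[label_column]]
  feats <- df[, setdiff(names(df), label_column), drop = FALSE]
  if (ncol(feats) < 1L) {
    stop("no feature columns left after removing the label column",
         call. = FALSE)
  }
  for (nm in names(feats)) {
    col <- feats[[nm]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(parsed) & !is.na(col) & !(trimws(col) %in% c("NA", "")))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     nm, bad[1], col[bad[1]]), call. = FALSE)
      }
      col <- parsed
    }
    if (anyNA(col)) {
      if (!impute) {
        stop(sprintf(
          "missing value in column '%s', row %d (set impute = TRUE to mean-impute)",
          nm, which(is.na(col))[1]), call. = FALSE)
      }
      col[is.na(col)] <- mean(col, na.rm = TRUE)
    }
    feats[[nm]] <- col
  }
  data <- feature_matrix(as.matrix(feats), labels, names(feats))
  check_trainable(data)
  data
}

#' Specification for a synthetic benchmark dataset
#'
#' Describes a planted-ground-truth classification dataset: a few informative
#' features whose class means are separated, optional noisy redundant copies
#' of them, and many label-independent noise features — the structure of
#' real benchmarks where most measured variables are meaningless for the
#' outcome (e.g. microarray panels with a handful of discriminative genes).
#'
#' @param n_samples Number of samples.
#' @param n_informative Number of informative features (class-separated
#'   means); at least 1.
#' @param n_redundant Number of redundant features, each a noisy copy of a
#'   randomly chosen informative feature.
#' @param n_noise Number of pure-noise features, standard normal draws
#'   independent of the label.
#' @param n_classes Number of classes (>= 2).
#' @param class_separation Distance between adjacent class means on each
#'   informative feature, in units of the noise standard deviation.
#' @param seed Integer seed; the full spec (including the seed) determines
#'   the dataset bit for bit.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 200, n_informative = 5,
                           n_redundant = 0, n_noise = 45, n_classes = 2,
                           class_separation = 3, seed = 1) {
  spec <- list(n_samples = as.integer(n_samples),
               n_informative = as.integer(n_informative),
               n_redundant = as.integer(n_redundant),
               n_noise = as.integer(n_noise),
               n_classes = as.integer(n_classes),
               class_separation = as.numeric(class_separation),
               seed = as.integer(seed))
  if (spec$n_informative < 1L) {
    stop("n_informative must be at least 1", call. = FALSE)
  }
  if (spec$n_redundant < 0L || spec$n_noise < 0L) {
    stop("n_redundant and n_noise must be non-negative", call. = FALSE)
  }
  if (spec$n_classes < 2L) {
    stop("n_classes must be at least 2", call. = FALSE)
  }
  if (spec$n_classes > spec$n_samples) {
    stop("n_classes cannot exceed n_samples", call. = FALSE)
  }
  if (spec$class_separation < 0) {
    stop("class_separation must be non-negative", call. = FALSE)
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic dataset with planted informative features
#'
#' Class labels are balanced across `n_classes`. Informative feature `j` has
#' per-class means `s_j * (c - 1) * class_separation` for class `c`, with a
#' random sign `s_j` and unit-variance Gaussian noise. Redundant features are
#' a randomly chosen informative column plus Gaussian noise with standard
#' deviation `0.5 * class_separation`. Noise features are standard normal.
#' The same spec always yields the same dataset.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `data` (a [feature_matrix()]) and `informative`
#'   (integer indices of the truly informative features, always
#'   `1:n_informative`).
#' @export
make_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  p <- spec$n_informative + spec$n_redundant + spec$n_noise
  stream <- new_rng_stream(spec$seed)
  with_stream(stream, {
    labels <- sample(rep_len(seq_len(spec$n_classes), n))
    values <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
    signs <- sample(c(-1, 1), spec$n_informative, replace = TRUE)
    for (j in seq_len(spec$n_informative)) {
      values[, j] <- values[, j] +
        signs[j] * (labels - 1) * spec$class_separation
    }
    if (spec$n_redundant > 0L) {
      parents <- sample(spec$n_informative, spec$n_redundant, replace = TRUE)
      for (k in seq_len(spec$n_redundant)) {
        col <- spec$n_informative + k
        values[, col] <- values[, parents[k]] +
          stats::rnorm(n, sd = 0.5 * spec$class_separation)
      }
    }
  })
  nm <- c(sprintf("inf%02d", seq_len(spec$n_informative)),
          if (spec$n_redundant > 0L) sprintf("red%02d", seq_len(spec$n_redundant)),
          if (spec$n_noise > 0L) sprintf("noise%02d", seq_len(spec$n_noise)))
  data <- feature_matrix(values, paste0("class", labels), nm)
  list(data = data, informative = seq_len(spec$n_informative))
}

#' Build a run report
#'
#' A serialisable summary of one selection run: the configuration used, the
#' finally selected feature names, the best-reward episode and its mask, and
#' the seeds, so that the run can be reproduced.
#'
#' @param config Named list echoing the run configuration, including a
#'   `feature_names` element listing every feature in the dataset.
#' @param selected_features Character vector of finally selected names (may
#'   be empty).
#' @param best_episode Episode index achieving the highest main reward.
#' @param best_mask Integer 0/1 vector, the mask of that episode.
#' @param seeds Named list of seeds used.
#' @param history_path Optional path of the per-episode history CSV.
#' @return A `marfs_report` object.
#' @export
run_report <- function(config, selected_features, best_episode = NA_integer_,
                       best_mask = integer(), seeds = list(),
                       history_path = NULL) {
  report <- structure(
    list(config = config,
         selected_features = as.character(selected_features),
         best_episode = best_episode,
         best_mask = as.integer(best_mask),
         seeds = seeds,
         history_path = history_path),
    class = "marfs_report"
  )
  validate_report(report)
  report
}

validate_report <- function(report) {
  fn <- report$config$feature_names
  if (!is.null(fn) &&
      !all(report$selected_features %in% fn)) {
    stop("report lists selected features absent from its config echo",
         call. = FALSE)
  }
  invisible(report)
}

#' Write / read a run report as JSON
#'
#' `read_report(write_report(x, path))` returns an object equal to `x`;
#' reports failing their own invariants are rejected on read.
#'
#' @param report A `marfs_report`.
#' @param path Output (or input) file path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the `marfs_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "marfs_report"))
  validate_report(report)
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  report <- structure(
    list(config = as.list(raw$config),
         selected_features = as.character(raw$selected_features %||% character()),
         best_episode = if (is.null(raw$best_episode)) NA_integer_ else
           as.integer(raw$best_episode),
         best_mask = as.integer(raw$best_mask %||% integer()),
         seeds = as.list(raw$seeds %||% list()),
         history_path = raw$history_path),
    class = "marfs_report"
  )
  validate_report(report)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a per-episode history table as CSV
#'
#' Columns: `episode, epsilon, r_main, r_guide, r_train, n_selected_main,
#' n_selected_guide`. Ablation runs (no guide) carry `NA` in the guide
#' columns.
#'
#' @param history Data frame as found in `marfs_result$history`.
#' @param path Output path.
#' @export
write_history <- function(history, path) {
  cols <- c("episode", "epsilon", "r_main", "r_guide", "r_train",
            "n_selected_main", "n_selected_guide")
  stopifnot(all(cols %in% names(history)))
  utils::write.csv(history[, cols], path, row.names = FALSE)
  invisible(path)
}
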