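#' Classifier configuration for the reward environment
#'
#' The reward for a candidate feature subset is the holdout accuracy of a
#' small feed-forward network trained from scratch on that subset. The
#' defaults are a network with two hidden layers of five and two ReLU
#' units, learning rate 0.01, and at most 10 passes over the training data,
#' optimised with mini-batch Adam.
#'
#' @param hidden_layer_sizes Integer vector of hidden-layer widths.
#' @param activation Hidden activation; only `"relu"` is built in.
#' @param learning_rate Adam step size.
#' @param max_epochs Number of passes over the training data (no early
#'   stopping).
#' @param batch_size Mini-batch size (capped at the training-set size).
#' @param optimizer_seed Integer seed for weight initialisation and batch
#'   shuffling; `NULL` means the caller (e.g. [marfs_fit()]) supplies one
#'   per evaluation.
#' @param classifier Optional replacement classifier: a
#'   `function(x_train, y_train, x_test, seed)` returning predicted labels
#'   for `x_test` (a factor or character vector on the levels of
#'   `y_train`). When supplied, the built-in network is bypassed.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(hidden_layer_sizes = c(5, 2),
                              activation = "relu",
                              learning_rate = 0.01,
                              max_epochs = 10,
                              batch_size = 32,
                              optimizer_seed = NULL,
                              classifier = NULL) {
  if (!identical(activation, "relu")) {
    stop("only the 'relu' activation is built in", call. = FALSE)
  }
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (max_epochs < 1) stop("max_epochs must be at least 1", call. = FALSE)
  structure(
    list(hidden_layer_sizes = as.integer(hidden_layer_sizes),
         activation = activation,
         learning_rate = as.numeric(learning_rate),
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size),
         optimizer_seed = optimizer_seed,
         classifier = classifier),
    class = "classifier_config"
  )
}

#' Train/test split specification
#'
#' One split is computed per run, before the episode loop, and reused for
#' every reward evaluation; resplitting per episode would confound the
#' learning signal.
#'
#' @param train_fraction Fraction of samples in the training part
#'   (default 0.7, i.e. a 7:3 split).
#' @param stratified Stratify by class (default `TRUE`), so small classes
#'   are present on both sides.
#' @param seed Integer seed for the split; `NULL` lets [marfs_fit()] derive
#'   one from its master seed.
#' @return A `split_spec` list.
#' @export
split_spec <- function(train_fraction = 0.7, stratified = TRUE, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(train_fraction = as.numeric(train_fraction),
         stratified = isTRUE(stratified),
         seed = seed),
    class = "split_spec"
  )
}

#' Split a dataset into training and test parts
#'
#' @param data A [feature_matrix()].
#' @param spec A [split_spec()]; `spec$seed` must be set (directly or by the
#'   caller).
#' @return A list with `train` and `test` (both `feature_matrix`) and the
#'   index vectors `train_idx`, `test_idx` (a disjoint, exhaustive
#'   partition of the samples).
#' @export
split_dataset <- function(data, spec) {
  stopifnot(inherits(data, "feature_matrix"), inherits(spec, "split_spec"))
  check_trainable(data)
  seed <- spec$seed
  if (is.null(seed)) stop("split_spec$seed is not set", call. = FALSE)
  n <- n_samples(data)
  stream <- new_rng_stream(as.integer(seed))
  train_idx <- with_stream(stream, {
    if (spec$stratified) {
      idx <- unlist(lapply(split(seq_len(n), data$labels), function(members) {
        k <- round(length(members) * spec$train_fraction)
        k <- max(1L, min(length(members) - 1L, k))
        sample(members, k)
      }), use.names = FALSE)
      sort(idx)
    } else {
      sort(sample(n, round(n * spec$train_fraction)))
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  if (!length(train_idx) || !length(test_idx)) {
    stop("split leaves one part empty; adjust train_fraction", call. = FALSE)
  }
  part <- function(idx) feature_matrix(data$values[idx, , drop = FALSE],
                                       data$labels[idx], data$feature_names)
  out <- list(train = part(train_idx), test = part(test_idx),
              train_idx = train_idx, test_idx = test_idx)
  if (spec$stratified) {
    if (nlevels(droplevels(out$train$labels)) < nlevels(droplevels(data$labels))) {
      stop("a class is absent from the training part under stratification",
           call. = FALSE)
    }
  }
  out
}

#' Majority-class accuracy of a label vector
#'
#' The fallback reward when a mask selects no features: a classifier with no
#' inputs can do no better than always predicting the modal class.
#'
#' @param labels Non-empty vector of class labels.
#' @return Frequency of the most common class, in `[0, 1]`.
#' @export
majority_baseline <- function(labels) {
  if (!length(labels)) stop("labels must be non-empty", call. = FALSE)
  max(table(labels)) / length(labels)
}

#' Accuracy reward of a feature subset
#'
#' Trains a fresh classifier on the training part restricted to the selected
#' columns and returns the fraction of correct predictions on the test
#' part. Features are standardised (zero mean, unit variance) using
#' training-part statistics only. An empty mask is legal and falls back to
#' the majority-class test accuracy.
#'
#' @param train,test Feature matrices from [split_dataset()].
#' @param mask Integer/logical 0-1 vector of length `n_features`.
#' @param cfg A [classifier_config()]; its `optimizer_seed` must be set by
#'   the caller (or left at a fixed default) for reproducibility.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_subset <- function(train, test, mask, cfg = classifier_config()) {
  mask <- as.integer(mask)
  if (length(mask) != train$n_features) {
    stop("mask length must equal the number of features", call. = FALSE)
  }
  if (!all(mask %in% c(0L, 1L))) {
    stop("mask entries must be 0 or 1", call. = FALSE)
  }
  sel <- which(mask == 1L)
  if (!length(sel)) {
    return(majority_baseline(test$labels))
  }
  xtr <- train$values[, sel, drop = FALSE]
  xte <- test$values[, sel, drop = FALSE]
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")

  levels_all <- levels(train$labels)
  seed <- cfg$optimizer_seed %||% 1L

  if (!is.null(cfg$classifier)) {
    pred <- cfg$classifier(xtr, train$labels, xte, seed)
    return(mean(as.character(pred) == as.character(test$labels)))
  }

  ytr <- as.integer(train$labels) - 1L
  pred <- mlp_fit_predict_cpp(xtr, ytr, xte,
                              n_classes = length(levels_all),
                              hidden = cfg$hidden_layer_sizes,
                              lr = cfg$learning_rate,
                              epochs = cfg$max_epochs,
                              batch_size = cfg$batch_size,
                              seed = as.integer(seed))
  mean(levels_all[pred + 1L] == as.character(test$labels))
}

#' Deterministic per-mask subset accuracy
#'
#' The value function used by cached runs: the optimizer seed is derived
#' from the mask bits and a base seed, so the accuracy of a given mask is a
#' fixed, reproducible number within a run — the same mask always scores
#' the same. Enumeration oracles evaluate candidate masks through this
#' function to compare against a cached run on identical footing.
#'
#' @inheritParams evaluate_subset
#' @param base_seed Integer; a cached [marfs_fit()] run uses its
#'   `master_seed` here.
#' @return Accuracy in `[0, 1]`.
#' @export
cached_accuracy <- function(train, test, mask, cfg = classifier_config(),
                            base_seed = 1L) {
  cfg$optimizer_seed <- derive_seed(base_seed, 100L + mask_hash(mask))
  evaluate_subset(train, test, mask, cfg)
}
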