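# Comparator feature-selection methods: a filter ranking (mRMR), an
# instance-based weighting (ReliefF) and a wrapper genetic algorithm that
# shares the reward environment with the multi-agent selector.

# Equal-frequency discretisation into `bins` levels. Features with at most
# `bins` distinct values are already discrete and are used as-is (quantile
# breaks would merge their levels); constant columns collapse to one level.
discretize_ef <- function(x, bins = 5L) {
  if (length(unique(x)) <= bins) return(factor(x))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(qs) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

# Mutual information (nats) of two discrete vectors from their contingency
# table.
mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' mRMR feature ranking
#'
#' Greedy forward ranking under the mutual-information difference (MID)
#' criterion: the first feature maximises relevance `I(f; label)`; each
#' subsequent pick maximises relevance minus the mean mutual information
#' with the already-chosen features. Continuous features are discretised
#' into five equal-frequency bins before estimating mutual information.
#'
#' @param data A [feature_matrix()].
#' @param k Number of features to rank, `1 <= k <= n_features`.
#' @param bins Number of discretisation bins.
#' @return A `feature_ranking`: data frame with columns `rank`, `index`,
#'   `name`, `score` (the MID criterion value at selection time).
#' @export
mrmr_rank <- function(data, k, bins = 5L) {
  stopifnot(inherits(data, "feature_matrix"))
  N <- data$n_features
  if (k < 1 || k > N) {
    stop(sprintf("k must be between 1 and %d", N), call. = FALSE)
  }
  disc <- lapply(seq_len(N), function(j) discretize_ef(data$values[, j], bins))
  y <- data$labels
  relevance <- vapply(disc, mutual_information, numeric(1), y = y)

  chosen <- integer(0)
  scores <- numeric(0)
  # pairwise feature MI computed lazily
  red <- matrix(NA_real_, N, N)
  remaining <- seq_len(N)
  for (step in seq_len(k)) {
    crit <- vapply(remaining, function(j) {
      if (!length(chosen)) return(relevance[j])
      for (g in chosen) {
        if (is.na(red[j, g])) {
          red[j, g] <<- red[g, j] <<- mutual_information(disc[[j]], disc[[g]])
        }
      }
      relevance[j] - mean(red[j, chosen])
    }, numeric(1))
    best <- remaining[which.max(crit)]
    scores <- c(scores, max(crit))
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
  }
  structure(
    data.frame(rank = seq_len(k), index = chosen,
               name = data$feature_names[chosen], score = scores),
    class = c("feature_ranking", "data.frame")
  )
}

#' ReliefF feature weights
#'
#' Instance-based weighting handling multi-class data: for each sampled
#' instance, feature weights decrease with the distance to `n_neighbors`
#' nearest hits (same class) and increase with the class-prior-weighted
#' distance to the nearest misses of every other class. Features are
#' min-max scaled to `[0, 1]` before distances, so weights are invariant to
#' affine rescaling of any feature.
#'
#' @param data A [feature_matrix()].
#' @param n_neighbors Number of near hits/misses per class (default 10);
#'   every class must have more members than this.
#' @param n_iterations Number of instances sampled; `NULL` (default) uses
#'   every instance once.
#' @param seed Seed for instance sampling (only used when `n_iterations`
#'   is smaller than the sample count).
#' @return A `feature_ranking` data frame (`rank`, `index`, `name`,
#'   `score`), sorted by decreasing weight, covering all features.
#' @export
relief_weights <- function(data, n_neighbors = 10, n_iterations = NULL,
                           seed = 1) {
  stopifnot(inherits(data, "feature_matrix"))
  check_trainable(data)
  n <- n_samples(data)
  N <- data$n_features
  k <- as.integer(n_neighbors)
  if (k < 1) stop("n_neighbors must be at least 1", call. = FALSE)
  class_sizes <- table(data$labels)
  if (any(class_sizes <= k)) {
    small <- names(class_sizes)[class_sizes <= k][1]
    stop(sprintf(
      "class '%s' has %d members; ReliefF with %d neighbors needs more than %d per class",
      small, class_sizes[small], k, k), call. = FALSE)
  }

  x <- data$values
  rng <- apply(x, 2, function(col) {
    r <- diff(range(col))
    if (r == 0 || !is.finite(r)) 1 else r
  })
  x <- sweep(sweep(x, 2, apply(data$values, 2, min)), 2, rng, "/")

  y <- data$labels
  priors <- as.numeric(class_sizes) / n
  names(priors) <- names(class_sizes)

  m <- if (is.null(n_iterations)) n else as.integer(n_iterations)
  picks <- if (m >= n) seq_len(n) else {
    with_stream(new_rng_stream(as.integer(seed)), sample(n, m))
  }

  by_class <- split(seq_len(n), y)
  w <- numeric(N)
  for (i in picks) {
    d <- rowSums(abs(sweep(x, 2, x[i, ], "-"))) # manhattan distance
    ci <- as.character(y[i])
    hits <- setdiff(by_class[[ci]], i)
    hit_idx <- hits[order(d[hits])][seq_len(k)]
    w <- w - colMeans(abs(sweep(x[hit_idx, , drop = FALSE], 2, x[i, ], "-"))) / m
    for (cl in setdiff(names(by_class), ci)) {
      miss <- by_class[[cl]]
      miss_idx <- miss[order(d[miss])][seq_len(k)]
      wt <- priors[[cl]] / (1 - priors[[ci]])
      w <- w + wt *
        colMeans(abs(sweep(x[miss_idx, , drop = FALSE], 2, x[i, ], "-"))) / m
    }
  }
  ord <- order(w, decreasing = TRUE)
  structure(
    data.frame(rank = seq_len(N), index = ord,
               name = data$feature_names[ord], score = w[ord]),
    class = c("feature_ranking", "data.frame")
  )
}

#' Genetic-algorithm configuration
#'
#' A deliberately basic bitmask GA: tournament selection, uniform
#' crossover, per-bit mutation, elitism. The defaults (population 50,
#' tournament 3, crossover 0.9, mutation 1/N, one elite) are this package's
#' choices, not fixed by any reference.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param crossover_rate Probability a parent pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-bit flip probability; `NULL` means `1/N`.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Number of top individuals copied unchanged (>= 1).
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50, generations = 30,
                      crossover_rate = 0.9, mutation_rate = NULL,
                      tournament_size = 3, elitism = 1, seed = 1) {
  if (population_size < 2) stop("population_size must be >= 2", call. = FALSE)
  if (elitism < 1) stop("elitism must be >= 1", call. = FALSE)
  if (!is.null(mutation_rate) &&
      (mutation_rate < 0 || mutation_rate >= 1)) {
    stop("mutation_rate must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_rate = as.numeric(crossover_rate),
         mutation_rate = mutation_rate,
         tournament_size = as.integer(tournament_size),
         elitism = as.integer(elitism),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Wrapper feature selection with a basic genetic algorithm
#'
#' Fitness is the same holdout classification accuracy used by the
#' multi-agent selector ([evaluate_subset()] on one fixed split with the
#' same classifier configuration). Returns the best individual ever seen.
#'
#' @param data A [feature_matrix()].
#' @param cfg A [ga_config()].
#' @param clf A [classifier_config()].
#' @param split A [split_spec()]; a `NULL` seed is derived from `cfg$seed`.
#' @param cache Memoise fitness by mask within the run (default `TRUE`;
#'   the GA revisits masks often).
#' @return A `ga_result` list: `best_mask`, `best_fitness`,
#'   `selected_features`, and `history` (per generation: best of the
#'   generation and best so far).
#' @export
ga_select <- function(data, cfg = ga_config(), clf = classifier_config(),
                      split = split_spec(), cache = TRUE) {
  stopifnot(inherits(data, "feature_matrix"), inherits(cfg, "ga_config"))
  check_trainable(data)
  N <- data$n_features
  mut <- cfg$mutation_rate %||% (1 / N)
  if (is.null(split$seed)) {
    split$seed <- derive_seed(cfg$seed, STREAM_OFFSETS[["split"]])
  }
  parts <- split_dataset(data, split)
  streams <- rng_streams(cfg$seed, which = c("ga", "classifier"))
  memo <- if (isTRUE(cache)) new.env(parent = emptyenv()) else NULL

  fitness <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(memo)) {
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
    }
    cfg2 <- clf
    cfg2$optimizer_seed <- stream_int(streams$classifier)
    acc <- evaluate_subset(parts$train, parts$test, mask, cfg2)
    if (!is.null(memo)) memo[[key]] <- acc
    acc
  }

  P <- cfg$population_size
  pop <- with_stream(streams$ga,
                     matrix(as.integer(stats::runif(P * N) < 0.5), P, N))
  fit <- apply(pop, 1, fitness)
  best_mask <- pop[which.max(fit), ]
  best_fit <- max(fit)
  hist_best <- numeric(cfg$generations)
  hist_sofar <- numeric(cfg$generations)

  for (g in seq_len(cfg$generations)) {
    newpop <- with_stream(streams$ga, {
      np <- matrix(0L, P, N)
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(cfg$elitism)]
      np[seq_len(cfg$elitism), ] <- pop[elite_idx, , drop = FALSE]
      row <- cfg$elitism
      tournament <- function() {
        cand <- sample(P, cfg$tournament_size, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      while (row < P) {
        p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
        if (stats::runif(1) < cfg$crossover_rate) {
          swap <- stats::runif(N) < 0.5
          c1 <- ifelse(swap, p2, p1); c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1; c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (row >= P) break
          flip <- stats::runif(N) < mut
          child[flip] <- 1L - child[flip]
          row <- row + 1
          np[row, ] <- child
        }
      }
      np
    })
    pop <- newpop
    fit <- apply(pop, 1, fitness)
    gen_best <- max(fit)
    if (gen_best > best_fit) {
      best_fit <- gen_best
      best_mask <- pop[which.max(fit), ]
    }
    hist_best[g] <- gen_best
    hist_sofar[g] <- best_fit
  }
  structure(
    list(best_mask = as.integer(best_mask),
         best_fitness = best_fit,
         selected_features = data$feature_names[best_mask == 1L],
         history = data.frame(generation = seq_len(cfg$generations),
                              best_of_generation = hist_best,
                              best_so_far = hist_sofar),
         config = cfg),
    class = "ga_result"
  )
}

#' Convert a ranking to the best top-k subset
#'
#' Ranked filter methods do not fix a subset size; following common
#' practice the top-k prefixes are evaluated with the shared reward
#' environment and the most accurate one is reported.
#'
#' @param ranking A `feature_ranking` (from [mrmr_rank()] or
#'   [relief_weights()]).
#' @param data The [feature_matrix()] the ranking was computed on.
#' @param ks Integer vector of subset sizes to try; `NULL` tries every
#'   prefix up to the ranking length (capped at 25 grid points for long
#'   rankings).
#' @param clf A [classifier_config()].
#' @param split A [split_spec()] with a set seed.
#' @return List with `k`, `mask`, `accuracy` and the per-k `grid`.
#' @export
best_topk <- function(ranking, data, ks = NULL, clf = classifier_config(),
                      split = split_spec(seed = 1)) {
  stopifnot(inherits(ranking, "feature_ranking"))
  kmax <- nrow(ranking)
  if (is.null(ks)) {
    ks <- if (kmax <= 25) seq_len(kmax) else
      unique(round(seq(1, kmax, length.out = 25)))
  }
  parts <- split_dataset(data, split)
  accs <- vapply(ks, function(k) {
    mask <- integer(data$n_features)
    mask[ranking$index[seq_len(k)]] <- 1L
    evaluate_subset(parts$train, parts$test, mask, clf)
  }, numeric(1))
  kbest <- ks[which.max(accs)]
  mask <- integer(data$n_features)
  mask[ranking$index[seq_len(kbest)]] <- 1L
  list(k = kbest, mask = mask, accuracy = max(accs),
       grid = data.frame(k = ks, accuracy = accs))
}
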