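# Shared fixtures, all generated in code.

# The standard planted benchmark used across tests: 5 informative features
# with 3-sigma class separation, 45 pure-noise features, 200 samples.
planted_data <- function(seed = 1, n_samples = 200, n_informative = 5,
                         n_noise = 45, class_separation = 3, ...) {
  make_synthetic(synthetic_spec(
    n_samples = n_samples, n_informative = n_informative,
    n_noise = n_noise, class_separation = class_separation,
    seed = seed, ...))
}

# Write a small feature table to a temp CSV and return its path.
write_temp_csv <- function(df, file = tempfile(fileext = ".csv")) {
  utils::write.csv(df, file, row.names = FALSE)
  file
}

# Independent one-feature threshold classifier: train a midpoint cut on the
# training part, score on the test part. Used as an oracle for the network
# environment on perfectly separated data.
threshold_accuracy <- function(train, test, feature) {
  xtr <- train$values[, feature]
  cls <- levels(train$labels)
  m1 <- mean(xtr[train$labels == cls[1]])
  m2 <- mean(xtr[train$labels == cls[2]])
  cut <- (m1 + m2) / 2
  pred <- ifelse((test$values[, feature] > cut) == (m2 > m1), cls[2], cls[1])
  mean(pred == as.character(test$labels))
}

# Discrete mutual information computed directly from the definition, as an
# oracle independent of the package's estimator.
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        pij <- tab[i, j] / n
        mi <- mi + pij * log(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  mi
}
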