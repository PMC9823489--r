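test_that("agent initialisation respects the asymmetric ranges", {
  cfg <- run_config(master_seed = 1)
  set.seed(42)
  q <- init_agents(30, cfg)
  expect_equal(dim(q), c(30L, 2L)) # one main agent per feature
  expect_true(all(q[, "q0"] >= 0 & q[, "q0"] <= 1))
  expect_true(all(q[, "q1"] >= 0 & q[, "q1"] <= 0.05))
  expect_error(init_agents(0, cfg), "at least one")
})

test_that("asymmetric init selects ~2.5% of features initially", {
  # P(U(0, 0.05) >= U(0, 1)) = 0.025 in closed form; Monte-Carlo check
  cfg <- run_config(master_seed = 1)
  set.seed(7)
  q <- init_agents(1e6, cfg)
  frac <- mean(greedy_selection(q))
  expect_equal(frac, 0.025, tolerance = 0.1) # relative: 0.0225..0.0275
})

test_that("pure exploitation follows the Q table, ties select", {
  q <- rbind(c(0.2, 0.7), c(0.7, 0.2), c(0.5, 0.5))
  set.seed(1)
  expect_identical(main_actions(q, epsilon = 0), c(1L, 0L, 1L))
  expect_error(main_actions(q, epsilon = 1.5), "epsilon")
})

test_that("pure exploration selects each feature about half the time", {
  q <- rbind(c(1, 0), c(0, 1)) # Q table must be ignored at epsilon = 1
  set.seed(99)
  draws <- replicate(10000, main_actions(q, epsilon = 1))
  freq <- rowMeans(draws)
  # 3-sigma binomial band around 0.5 for 10,000 draws is about +-0.015
  expect_true(all(abs(freq - 0.5) < 0.02))
})

test_that("guide actions are fair coins, independent across episodes", {
  set.seed(3)
  draws <- replicate(10000, guide_actions(4))
  expect_true(all(abs(rowMeans(draws) - 0.5) < 0.02))
  # successive episodes uncorrelated
  for (i in 1:4) {
    r <- cor(draws[i, -1], draws[i, -10000])
    expect_lt(abs(r), 0.05)
  }
  expect_error(guide_actions(0), "at least one")
})

test_that("train reward is the signed accuracy difference", {
  expect_equal(train_reward(0.9, 0.7), 0.2)
  expect_equal(train_reward(0.5, 0.5), 0.0)
  expect_equal(train_reward(0.3, 0.8), -0.5)
  expect_error(train_reward(1.2, 0.5), "\\[0, 1\\]")
  expect_error(train_reward(0.5, -0.1), "\\[0, 1\\]")
})

test_that("the Q update touches only acted cells at disagreeing positions", {
  q <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  out <- update_q(q, main = c(1L, 0L), guide = c(1L, 1L),
                  r_train = 0.2, alpha = 0.01)
  expect_equal(unname(out[1, ]), c(0.5, 0.5))   # agreement: untouched
  expect_equal(unname(out[2, 1]), 0.502)        # acted action (deselect)
  expect_equal(unname(out[2, 2]), 0.5)          # non-acted action: never

  # full agreement leaves the table unchanged for any reward
  same <- c(1L, 0L)
  expect_identical(update_q(q, same, same, r_train = 0.9, alpha = 0.5), q)
  # zero reward changes nothing even at disagreements
  expect_identical(update_q(q, c(1L, 0L), c(0L, 1L), 0, alpha = 0.1), q)
  expect_error(update_q(q, c(1L), c(0L, 1L), 0.1, 0.01), "mask length")
})

test_that("epsilon decay matches its closed form", {
  expect_equal(decay_epsilon(0.4, 1), 0.4)
  eps <- 0.5
  for (t in 1:250) eps <- decay_epsilon(eps, 0.999)
  expect_equal(eps, 0.5 * 0.999^250, tolerance = 1e-12)
  expect_error(decay_epsilon(2, 0.9), "epsilon")
  expect_error(decay_epsilon(0.5, 0), "edr")
})

test_that("edr_for reproduces the published decay settings", {
  expect_equal(edr_for(10000), 0.99995, tolerance = 1e-4)
  expect_equal(edr_for(1000), 0.9995, tolerance = 1e-4)
})

test_that("greedy selection is the row-wise argmax with ties selecting", {
  q <- rbind(c(0.3, 0.4), c(0.9, 0.1), c(0.2, 0.2))
  expect_identical(greedy_selection(q), c(1L, 0L, 1L))
})

test_that("episode records satisfy the reward algebra", {
  synth <- planted_data(seed = 2, n_samples = 80, n_noise = 10)
  parts <- split_dataset(synth$data, split_spec(seed = 1))
  env <- list(train = parts$train, test = parts$test)
  cfg <- run_config(master_seed = 5, n_episodes = 10)
  clf <- classifier_config()
  streams <- marfsga:::rng_streams(5)
  set.seed(123)
  q <- init_agents(synth$data$n_features, cfg)
  out <- run_episode(q, epsilon = 0.5, env, cfg, clf, streams)
  rec <- out$record
  expect_equal(rec$r_train, rec$r_main - rec$r_guide)
  expect_gte(rec$r_main, 0); expect_lte(rec$r_main, 1)
  expect_gte(rec$r_guide, 0); expect_lte(rec$r_guide, 1)
  expect_equal(rec$n_selected_main, sum(rec$main))
  expect_equal(rec$n_selected_guide, sum(rec$guide))
})

test_that("the ablation rewards every acted Q with alpha * r_main", {
  synth <- planted_data(seed = 2, n_samples = 80, n_noise = 10)
  parts <- split_dataset(synth$data, split_spec(seed = 1))
  env <- list(train = parts$train, test = parts$test)
  cfg <- run_config(master_seed = 5, guide_enabled = FALSE)
  streams <- marfsga:::rng_streams(5)
  set.seed(123)
  q <- init_agents(synth$data$n_features, cfg)
  out <- run_episode(q, epsilon = 0.5, env, cfg, classifier_config(), streams)
  rec <- out$record
  expect_true(is.na(rec$r_guide))
  expect_true(is.na(rec$r_train))
  delta <- out$agents - q
  acted <- cbind(seq_along(rec$main), rec$main + 1L)
  expect_true(all(abs(delta[acted] - cfg$alpha * rec$r_main) < 1e-12))
  delta[acted] <- 0
  expect_true(all(delta == 0)) # non-acted cells untouched
})

test_that("full runs are deterministic given the master seed", {
  synth <- planted_data(seed = 3, n_samples = 60, n_noise = 6)
  cfg <- run_config(n_episodes = 30, master_seed = 21, cache = TRUE)
  a <- marfs_fit(synth$data, cfg)
  b <- marfs_fit(synth$data, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$agents, b$agents)
  expect_identical(a$greedy_mask, b$greedy_mask)
})

test_that("recorded epsilon follows the closed-form schedule", {
  synth <- planted_data(seed = 3, n_samples = 60, n_noise = 6)
  cfg <- run_config(n_episodes = 40, epsilon0 = 0.5, edr = 0.99,
                    master_seed = 2, cache = TRUE)
  res <- marfs_fit(synth$data, cfg)
  expect_equal(res$history$epsilon, 0.5 * 0.99^(0:39), tolerance = 1e-12)
})

test_that("a single-feature dataset runs without index errors", {
  synth <- make_synthetic(synthetic_spec(
    n_samples = 60, n_informative = 1, n_noise = 0,
    class_separation = 5, seed = 4))
  res <- marfs_fit(synth$data,
                   run_config(n_episodes = 25, master_seed = 1, cache = TRUE))
  expect_length(res$greedy_mask, 1L)
  expect_equal(nrow(res$history), 25L)
  expect_true(all(res$history$n_selected_main %in% 0:1))
})

test_that("an unreachable stop target runs all episodes; a reachable one stops early", {
  synth <- planted_data(seed = 3, n_samples = 60, n_noise = 6)
  res <- marfs_fit(synth$data,
                   run_config(n_episodes = 20, master_seed = 1,
                              stop_target = 1.01, cache = TRUE))
  expect_equal(nrow(res$history), 20L)

  early <- marfs_fit(synth$data,
                     run_config(n_episodes = 500, master_seed = 1,
                                stop_target = 0.5, cache = TRUE))
  expect_lt(nrow(early$history), 500L)
  expect_gte(early$history$r_main[nrow(early$history)], 0.5)
})

test_that("the best-episode record matches the history maximum", {
  synth <- planted_data(seed = 6, n_samples = 60, n_noise = 6)
  res <- marfs_fit(synth$data,
                   run_config(n_episodes = 50, master_seed = 9, cache = TRUE))
  expect_equal(res$best_r_main, max(res$history$r_main))
  expect_equal(res$history$r_main[res$best_episode], res$best_r_main)
  expect_equal(sum(res$best_mask),
               res$history$n_selected_main[res$best_episode])
})

test_that("toggling the guide does not perturb the other random streams", {
  synth <- planted_data(seed = 3, n_samples = 60, n_noise = 6)
  with_g <- marfs_fit(synth$data,
                      run_config(n_episodes = 15, master_seed = 4, cache = TRUE))
  no_g <- marfs_fit(synth$data,
                    run_config(n_episodes = 15, master_seed = 4,
                               guide_enabled = FALSE, cache = TRUE))
  # same split and same first main action: init + exploration streams shared
  expect_identical(with_g$split_idx, no_g$split_idx)
  expect_equal(with_g$history$n_selected_main[1],
               no_g$history$n_selected_main[1])
})
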