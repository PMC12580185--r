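test_that("mode choice degenerates correctly at probability extremes", {
  set.seed(1)
  m0 <- replicate(50, unlist(choose_update_mode(0, 0)))
  expect_false(any(m0))
  m1 <- replicate(50, unlist(choose_update_mode(1, 1)))
  expect_true(all(m1))
})

test_that("the four-mode update reduces to the classical rule without cross/elite", {
  set.seed(5)
  d <- 6
  x <- runif(d); v <- runif(d, -0.1, 0.1); w <- runif(d); mn <- runif(d)
  set.seed(99)
  a <- transfer_update(x, v, list(cross = FALSE, elite = FALSE), w,
                       own_elites = NULL, swarm_mean = mn, phi = 0.1)
  set.seed(99)
  b <- classical_loser_update(x, v, w, mn, phi = 0.1)
  expect_identical(a, b)
})

test_that("elite-mode fixed point and forced cross-task elite jump", {
  d <- 4
  x <- rep(0.3, d)
  pool_self <- structure(list(indices = 1L, pos = matrix(x, 1),
                              fit = 0.1, mean = x), class = "elite_pool")
  u <- transfer_update(x, rep(0, d), list(cross = FALSE, elite = TRUE),
                       winner_position = rep(0.9, d), own_elites = pool_self,
                       swarm_mean = rep(0.5, d), phi = 0.1)
  expect_equal(u$position, x)

  other <- structure(list(indices = 1L, pos = matrix(rep(0.8, d), 1),
                          fit = 0.05, mean = rep(0.8, d)),
                     class = "elite_pool")
  mask <- c(TRUE, TRUE, TRUE, FALSE)
  u2 <- transfer_update(x, rep(0, d), list(cross = TRUE, elite = TRUE),
                        winner_position = rep(0.9, d), own_elites = pool_self,
                        other_elites = other, swarm_mean = rep(0.5, d),
                        task_mask = mask,
                        r = list(r1 = rep(0, d), r2 = rep(0, d),
                                 r3 = rep(1, d)))
  expect_equal(u2$position, c(0.8, 0.8, 0.8, 0))
  expect_error(
    transfer_update(x, rep(0, d), list(cross = TRUE, elite = TRUE),
                    winner_position = x, own_elites = pool_self,
                    other_elites = NULL, swarm_mean = x),
    "elite pool required")
})

test_that("a fixed seed reproduces the whole run bit-identically", {
  df <- toy_data(n = 24, d = 10, seed = 3)
  f1 <- swarm_select(df, "class", pop_size = 8, max_iter = 6, seed = 42)
  f2 <- swarm_select(df, "class", pop_size = 8, max_iter = 6, seed = 42)
  expect_identical(f1$best_mask, f2$best_mask)
  expect_identical(f1$best_fitness, f2$best_fitness)
  expect_identical(f1$history, f2$history)
})

test_that("max_iter = 0 returns the best of the initial populations", {
  df <- toy_frame_for_engine()
  fit <- swarm_select(df, "class", pop_size = 6, max_iter = 0, seed = 7,
                      fitness_fun = toy_fitness)
  expect_equal(nrow(fit$history), 2)   # one row per task, generation 0
  expect_equal(fit$best_fitness, min(fit$history$best_fitness))
})

test_that("the best-so-far fitness never regresses across generations", {
  df <- toy_frame_for_engine()
  fit <- swarm_select(df, "class", pop_size = 9, max_iter = 15, seed = 11,
                      fitness_fun = toy_fitness)
  running <- fit$history |>
    dplyr::group_by(generation) |>
    dplyr::summarise(b = min(best_fitness)) |>
    dplyr::pull(b) |>
    cummin()
  expect_true(all(diff(running) <= 0))
  expect_equal(fit$best_fitness, min(running))
})

test_that("positions stay in bounds and off-task dimensions stay zero", {
  df <- toy_frame_for_engine()
  fit <- swarm_select(df, "class", pop_size = 8, max_iter = 10, seed = 13,
                      fitness_fun = toy_fitness, trace = TRUE)
  aux_mask <- fit$task_pair$auxiliary_mask
  for (g in seq_along(fit$trace)) {
    for (t in 1:2) {
      pos <- fit$trace[[g]][[t]]$pos
      expect_true(all(pos >= 0 & pos <= 1))
    }
    expect_true(all(fit$trace[[g]][[2]]$pos[, !aux_mask] == 0))
  }
})

test_that("the no-transfer variant never reads the other task", {
  df <- toy_frame_for_engine()
  fit <- swarm_select(df, "class", variant = "no_transfer", pop_size = 8,
                      max_iter = 10, seed = 17, fitness_fun = toy_fitness)
  expect_identical(fit$n_cross_reads, 0L)
  full <- swarm_select(df, "class", variant = "multitask", pop_size = 8,
                       max_iter = 10, seed = 17, fitness_fun = toy_fitness)
  expect_gt(full$n_cross_reads, 0L)
})

test_that("the single-task variant matches the standalone classical CSO oracle", {
  df <- toy_frame_for_engine(d = 12)
  fit <- swarm_select(df, "class", variant = "cso", pop_size = 7,
                      max_iter = 10, seed = 23, fitness_fun = toy_fitness,
                      trace = TRUE)
  ref <- oracle_cso(toy_fitness, d = 12, pop = 7, iters = 10, seed = 23)
  for (g in seq_along(ref)) {
    expect_identical(fit$trace[[g]][[1]]$pos, ref[[g]]$pos)
    expect_identical(fit$trace[[g]][[1]]$vel, ref[[g]]$vel)
    expect_identical(unname(fit$trace[[g]][[1]]$fit), unname(ref[[g]]$fit))
  }
})

test_that("empirical mode frequencies follow the Bernoulli product law", {
  set.seed(31)
  n <- 20000
  draws <- matrix(NA, n, 2)
  for (i in seq_len(n)) {
    m <- choose_update_mode(0.3, 0.7)
    draws[i, ] <- c(m$cross, m$elite)
  }
  p <- c(0.3 * 0.7, 0.3 * 0.3, 0.7 * 0.7, 0.7 * 0.3)
  obs <- c(mean(draws[, 1] & draws[, 2]), mean(draws[, 1] & !draws[, 2]),
           mean(!draws[, 1] & draws[, 2]), mean(!draws[, 1] & !draws[, 2]))
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(obs - p) <= 3 * se))
})
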