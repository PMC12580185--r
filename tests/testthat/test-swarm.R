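test_that("swarm initialization respects the task mask and the seed", {
  mask <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  set.seed(1)
  s1 <- init_swarm(mask, 6)
  expect_equal(dim(s1$pos), c(6, 5))
  expect_true(all(s1$pos[, !mask] == 0))
  expect_true(all(s1$pos >= 0 & s1$pos <= 1))
  expect_true(all(s1$vel == 0))
  expect_true(all(is.na(s1$fit)))
  set.seed(1)
  expect_identical(init_swarm(mask, 6), s1)
  expect_error(init_swarm(mask, 1), ">= 2")
})

test_that("pairing produces a perfect matching with fitness-ordered winners", {
  s <- init_swarm(rep(TRUE, 3), 2)
  s$fit <- c(0.2, 0.1)
  set.seed(2)
  m <- pair_particles(s)
  expect_equal(unname(m$pairs[1, "winner"]), 2)
  expect_true(is.na(m$leftover))

  s5 <- init_swarm(rep(TRUE, 3), 5)
  s5$fit <- c(0.5, 0.4, 0.3, 0.2, 0.1)
  set.seed(3)
  m5 <- pair_particles(s5)
  expect_equal(nrow(m5$pairs), 2)
  expect_false(is.na(m5$leftover))
  expect_setequal(c(as.vector(m5$pairs), m5$leftover), 1:5)

  # exact fitness tie: lower index wins
  st <- init_swarm(rep(TRUE, 2), 2)
  st$fit <- c(0.3, 0.3)
  set.seed(4)
  mt <- pair_particles(st)
  expect_equal(unname(mt$pairs[1, "winner"]), 1)

  s$fit[1] <- NA
  expect_error(pair_particles(s), "evaluated")
})

test_that("the classical loser update has the stated fixed points and jumps", {
  d <- 4
  x <- rep(0.5, d)
  # X_W = X_L = mean and V = 0: particle unchanged
  u <- classical_loser_update(x, rep(0, d), x, x, phi = 0.1)
  expect_equal(u$position, x)
  expect_equal(u$velocity, rep(0, d))
  # r1 = 1, r2 = r3 = 0: velocity kept, position advances by inertia
  v0 <- c(0.1, -0.2, 0, 0.05)
  u2 <- classical_loser_update(x, v0, rep(0.9, d), rep(0.4, d),
                               r = list(r1 = rep(1, d), r2 = rep(0, d),
                                        r3 = rep(0, d)))
  expect_equal(u2$velocity, v0)
  expect_equal(u2$position, x + v0)
  # r1 = 0, r2 = 1, r3 = 0, V = 0: loser jumps exactly to the winner
  w <- c(0.9, 0.2, 0.7, 0.3)
  u3 <- classical_loser_update(x, rep(0, d), w, rep(0.5, d),
                               r = list(r1 = rep(0, d), r2 = rep(1, d),
                                        r3 = rep(0, d)))
  expect_equal(u3$position, w)
  expect_error(classical_loser_update(x, rep(0, 3), w, x), "length")
})

test_that("updates clamp and re-zero non-candidate dimensions", {
  mask <- c(TRUE, TRUE, FALSE)
  u <- classical_loser_update(c(0.9, 0.1, 0), c(0.8, -0.9, 0.5),
                              c(1, 0, 0), c(1, 0, 0), task_mask = mask,
                              r = list(r1 = rep(1, 3), r2 = rep(1, 3),
                                       r3 = rep(1, 3)), phi = 1)
  expect_true(all(u$velocity >= -1 & u$velocity <= 1))
  expect_true(all(u$position >= 0 & u$position <= 1))
  expect_equal(u$position[3], 0)
})

test_that("elite selection keeps the lowest-fitness particles with index tie-breaks", {
  s <- init_swarm(rep(TRUE, 2), 3)
  s$fit <- c(0.3, 0.1, 0.2)
  e <- select_elites(s, 2)
  expect_equal(e$indices, c(2, 3))
  expect_equal(max(e$fit), 0.2)
  # fitness bound: every member <= every non-member
  expect_lte(max(e$fit), min(s$fit[-e$indices]))
  # K >= pop: whole swarm
  expect_equal(nrow(select_elites(s, 10)$pos), 3)
  # single-member pool mean equals that member's position
  e1 <- select_elites(s, 1)
  expect_equal(e1$mean, s$pos[2, ])
  expect_error(select_elites(s, 0), ">= 1")
})

test_that("expected loser position follows the closed-form CSO mean", {
  # phi = 0: E[X'] = X + 0.5 V + 0.5 (X_W - X), checked by Monte Carlo
  set.seed(77)
  d <- 3
  x <- c(0.4, 0.5, 0.6)
  v <- c(0.05, -0.05, 0)
  w <- c(0.6, 0.3, 0.5)
  n <- 10000
  acc <- matrix(0, n, d)
  for (i in seq_len(n)) {
    acc[i, ] <- classical_loser_update(x, v, w, x, phi = 0)$position
  }
  expected <- x + 0.5 * v + 0.5 * (w - x)
  se <- apply(acc, 2, stats::sd) / sqrt(n)
  expect_true(all(abs(colMeans(acc) - expected) <= 3 * se))
})
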