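test_that("position decoding thresholds and respects the task mask", {
  expect_equal(decode_mask(c(0.7, 0.5, 0.61), threshold = 0.6),
               c(TRUE, FALSE, TRUE))
  expect_equal(sum(decode_mask(rep(0, 5))), 0)
  mask <- c(TRUE, FALSE, TRUE)
  expect_false(any(decode_mask(c(0.9, 0.9, 0.1), mask)[!mask]))
})

test_that("balanced error averages per-class true-positive rates", {
  expect_equal(balanced_error(c(0, 1, 0, 1), c(0, 1, 0, 1))$balanced_error, 0)
  # TPRs 1.0 and 0.5 -> 0.25
  expect_equal(balanced_error(c(0, 0, 1, 1), c(0, 0, 1, 0))$balanced_error, 0.25)
  # hand-counted 3-class case: sizes (10,5,5), correct (9,4,1)
  truth <- rep(c("a", "b", "c"), c(10, 5, 5))
  est <- truth
  est[10] <- "b"; est[14] <- "c"
  est[16:19] <- "a"
  m <- balanced_error(truth, est)
  expect_equal(unname(m$tpr_per_class), c(0.9, 0.8, 0.2))
  expect_equal(m$balanced_error, 1 - 1.9 / 3, tolerance = 1e-12)
  expect_error(balanced_error(c("a", "a"), c("a", "b"), levels = c("a", "b")),
               "absent")
})

test_that("balanced error is invariant under relabeling and equals plain error when balanced", {
  set.seed(6)
  truth <- sample(0:2, 30, replace = TRUE)
  est <- truth
  est[sample(30, 8)] <- sample(0:2, 8, replace = TRUE)
  base <- balanced_error(truth, est)$balanced_error
  relab <- c(2, 0, 1)
  expect_equal(balanced_error(relab[truth + 1], relab[est + 1])$balanced_error,
               base)
  tb <- rep(0:1, each = 10)
  eb <- tb; eb[c(1, 5, 13)] <- 1 - eb[c(1, 5, 13)]
  expect_equal(balanced_error(tb, eb)$balanced_error, mean(tb != eb))
})

test_that("fitness arithmetic, monotonicity, and the empty-subset worst case", {
  expect_equal(fitness_score(0.25, 10, 100), 0.24999985, tolerance = 1e-12)
  expect_lt(abs(fitness_score(0, 100, 100) - 1e-6), 1e-10)
  expect_equal(fitness_score(0.3, 0, 100), 1)
  expect_lt(fitness_score(0.2, 10, 100), fitness_score(0.2, 20, 100))
  expect_lt(fitness_score(0.1, 10, 100), fitness_score(0.2, 10, 100))
  g <- fitness_score(runif(1), sample(100, 1), 100)
  expect_true(g >= 0 && g <= 1)
})

test_that("subset evaluation is cached, deterministic, and bounded", {
  df <- toy_data(n = 30, d = 6, seed = 10)
  sel <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  e1 <- evaluate_subset(df, "class", sel, seed = 3)
  e2 <- evaluate_subset(df, "class", sel, seed = 3)
  expect_identical(e1, e2)
  expect_true(e1$fitness >= 0 && e1$fitness <= 1)
  # empty subset gets the worst fitness
  e0 <- evaluate_subset(df, "class", rep(FALSE, 6), seed = 3)
  expect_equal(e0$fitness, 1)
  # the informative feature alone beats a noise feature alone
  ei <- evaluate_subset(df, "class", "f01", seed = 3)
  en <- evaluate_subset(df, "class", "f04", seed = 3)
  expect_lt(ei$fitness, en$fitness)
})

test_that("the built-in 1-NN matches class::knn where distance ties are absent", {
  set.seed(21)
  tr <- matrix(rnorm(40 * 5), 40)
  te <- matrix(rnorm(15 * 5), 15)
  y <- rep_len(1:2, 40)
  # z-score with training stats exactly as the package path does
  mu <- colMeans(tr); s <- sqrt(colMeans(tr^2) - mu^2)
  trz <- sweep(sweep(tr, 2, mu), 2, s, `/`)
  tez <- sweep(sweep(te, 2, mu), 2, s, `/`)
  ref <- as.integer(as.character(class::knn(trz, tez, factor(y), k = 1)))
  expect_equal(swarmsel:::nn1_predict(tr, y, te), ref)
})

test_that("a plug-in classifier is honored", {
  df <- toy_data(n = 24, d = 4, seed = 12)
  majority <- list(
    fit = function(x, y) names(which.max(table(y))),
    predict = function(model, x) rep(as.integer(model), nrow(x))
  )
  e <- evaluate_subset(df, "class", c(TRUE, TRUE, FALSE, FALSE),
                       classifier = majority, seed = 1)
  # majority vote on balanced classes: balanced error 0.5
  expect_equal(e$balanced_error, 0.5)
})

test_that("fold construction degrades gracefully for tiny classes", {
  df <- toy_data(n = 8, d = 4, seed = 13)   # class size 4 < 5 folds
  expect_warning(
    e <- evaluate_subset(df, "class", c(TRUE, TRUE, TRUE, FALSE), seed = 2),
    "reducing folds")
  expect_true(is.finite(e$fitness))
})
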