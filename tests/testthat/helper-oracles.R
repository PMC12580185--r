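# Independent brute-force oracles: naive loop implementations kept separate
# from the vectorized package code paths they validate.

oracle_fisher <- function(x, y, eps = 1e-12) {
  d <- ncol(x)
  out <- numeric(d)
  for (j in seq_len(d)) {
    mu <- mean(x[, j])
    num <- den <- 0
    for (c in unique(y)) {
      v <- x[y == c, j]
      num <- num + length(v) * (mean(v) - mu)^2
      den <- den + length(v) * mean((v - mean(v))^2)
    }
    out[j] <- num / (den + eps)
  }
  out
}

oracle_pcc <- function(x, y) {
  yn <- as.numeric(as.integer(factor(y)))
  vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) == 0) 0 else abs(stats::cor(x[, j], yn))
  }, numeric(1))
}

# Naive Relief-F: explicit per-instance, per-class neighbor sort over
# [0,1]-scaled features with Manhattan distances, ties by sample index.
oracle_relief <- function(x, y, k = 10) {
  n <- nrow(x)
  d <- ncol(x)
  xs <- x
  for (j in seq_len(d)) {
    r <- range(x[, j])
    xs[, j] <- if (r[2] > r[1]) (x[, j] - r[1]) / (r[2] - r[1]) else 0
  }
  prior <- table(factor(y)) / n
  w <- numeric(d)
  for (i in seq_len(n)) {
    dists <- vapply(seq_len(n), function(q) sum(abs(xs[i, ] - xs[q, ])),
                    numeric(1))
    for (c in sort(unique(y))) {
      members <- which(y == c)
      if (c == y[i]) members <- setdiff(members, i)
      if (length(members) == 0) next
      ord <- members[order(dists[members], members)]
      nb <- ord[seq_len(min(k, length(ord)))]
      dj <- numeric(d)
      for (q in nb) dj <- dj + abs(xs[i, ] - xs[q, ])
      dj <- dj / length(nb)
      if (c == y[i]) {
        w <- w - dj / n
      } else {
        pc <- as.numeric(prior[as.character(c)])
        pyi <- as.numeric(prior[as.character(y[i])])
        w <- w + (pc / (1 - pyi)) * dj / n
      }
    }
  }
  w
}

# Exhaustive max-perpendicular-distance knee search on (0..d-1, s).
oracle_knee <- function(s) {
  d <- length(s)
  x1 <- 0; y1 <- s[1]; x2 <- d - 1; y2 <- s[d]
  dist <- numeric(d)
  for (i in seq_len(d)) {
    xi <- i - 1
    dist[i] <- abs((y2 - y1) * xi - (x2 - x1) * (s[i] - y1)) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  }
  if (max(dist) <= 1e-12 * max(abs(s[1]), abs(s[d]), 1)) return(ceiling(d / 2))
  which.max(dist)
}

# Standalone classical competitive-swarm loop (pair winners + centroid pull
# only), written against the package's documented RNG stream layout: swarm
# init draws row-per-particle; per generation one pairing permutation; per
# loser two mode uniforms (discarded here -- the probabilities are zero),
# then r1, r2, r3 as length-d vectors. Returns per-generation state copies.
oracle_cso <- function(fitness_fun, d, pop, iters, phi = 0.1,
                       decode_threshold = 0.6, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(pop * d), nrow = pop, ncol = d, byrow = TRUE)
  vel <- matrix(0, pop, d)
  fit <- apply(pos, 1, function(p) fitness_fun(p > decode_threshold))
  trace <- list(list(pos = pos, vel = vel, fit = fit))
  for (g in seq_len(iters)) {
    mean_pos <- colMeans(pos)
    snap <- pos
    perm <- sample.int(pop)
    for (p in seq_len(pop %/% 2)) {
      a <- perm[2 * p - 1]; b <- perm[2 * p]
      if (fit[a] < fit[b] || (fit[a] == fit[b] && a < b)) {
        w <- a; l <- b
      } else {
        w <- b; l <- a
      }
      runif(2)                                   # mode draws, probabilities 0
      r1 <- runif(d); r2 <- runif(d); r3 <- runif(d)
      v <- r1 * vel[l, ] + r2 * (snap[w, ] - pos[l, ]) +
        phi * r3 * (mean_pos - pos[l, ])
      v <- pmin(pmax(v, -1), 1)
      x <- pmin(pmax(pos[l, ] + v, 0), 1)
      vel[l, ] <- v
      pos[l, ] <- x
      fit[l] <- fitness_fun(x > decode_threshold)
    }
    trace[[g + 1]] <- list(pos = pos, vel = vel, fit = fit)
  }
  trace
}

# Exact Wilcoxon signed-rank p-value by enumerating all sign assignments
# (two-sided), for small n without zeros or ties.
oracle_wilcoxon_exact <- function(diffs) {
  n <- length(diffs)
  rk <- rank(abs(diffs))
  v_obs <- sum(rk[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% rk)
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu))
}

# Small labeled toy data frame used across tests.
toy_data <- function(n = 20, d = 6, n_classes = 2, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  y <- rep_len(seq_len(n_classes) - 1, n)
  x[, 1] <- x[, 1] + 3 * y                       # one informative feature
  df <- as.data.frame(x)
  names(df) <- sprintf("f%02d", seq_len(d))
  df$class <- factor(y)
  tibble::as_tibble(df)
}

# Fixed 20-dimensional toy objective for engine tests: Hamming distance to a
# target mask plus a small size penalty.
toy_fitness <- function(sel) {
  target <- (seq_along(sel) %% 3) == 0
  mean(xor(sel, target)) + 1e-6 * mean(sel)
}

toy_frame_for_engine <- function(d = 20) {
  df <- as.data.frame(matrix(rnorm(4 * d), 4, d))
  names(df) <- sprintf("f%02d", seq_len(d))
  df$class <- factor(c(0, 1, 0, 1))
  tibble::as_tibble(df)
}
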