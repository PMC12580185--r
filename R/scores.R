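# Per-feature relevance scorers and their fusion.

#' Fisher score of each feature
#'
#' Ratio of between-class scatter to within-class scatter, computed per
#' feature: \deqn{F_j = \sum_c n_c (\mu_{c,j} - \mu_j)^2 /
#' (\sum_c n_c \sigma^2_{c,j} + \epsilon)} with class sizes \eqn{n_c}, class
#' means \eqn{\mu_{c,j}}, overall mean \eqn{\mu_j} and within-class
#' *population* variances \eqn{\sigma^2_{c,j}}. A constant feature scores 0.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param y Class labels (anything coercible to a factor), length `nrow(x)`.
#' @param eps Stabilizer added to the denominator so features with zero
#'   within-class variance get a large finite score instead of `Inf`.
#' @return Numeric vector of non-negative scores, one per feature.
#' @export
fisher_score <- function(x, y, eps = 1e-12) {
  x <- check_matrix(x)
  y <- as.integer(factor(y))
  check_labels(y)
  if (nrow(x) < 2L) stop("need >=2 samples", call. = FALSE)
  mu <- colMeans(x)
  num <- den <- numeric(ncol(x))
  for (c in unique(y)) {
    xc <- x[y == c, , drop = FALSE]
    nc <- nrow(xc)
    mc <- colMeans(xc)
    vc <- colMeans(xc * xc) - mc * mc   # population variance
    num <- num + nc * (mc - mu)^2
    den <- den + nc * vc
  }
  num / (den + eps)
}

#' Relief-F weights of each feature
#'
#' Standard Relief-F: features are min-max scaled to \[0,1\]; for each sampled
#' instance the algorithm finds its `k` nearest hits (same class, Manhattan
#' distance on the scaled features, self excluded) and `k` nearest misses in
#' each other class, subtracts the mean per-feature difference to the hits and
#' adds the class-prior-weighted mean difference to the misses. Weights are
#' averaged over the sampled instances. Distance ties are broken by sample
#' index so results are reproducible.
#'
#' @inheritParams fisher_score
#' @param k Number of neighbors per group (clamped to the available
#'   hits/misses when a class is smaller).
#' @param sample_size Number of instances to sample, or `NULL` (the default)
#'   to use every instance. Sampling uses the current RNG stream.
#' @return Numeric weight vector, one per feature; constant features weigh 0.
#' @export
relief_score <- function(x, y, k = 10, sample_size = NULL) {
  x <- check_matrix(x)
  y <- as.integer(factor(y))
  check_labels(y)
  n <- nrow(x)
  if (n < 2L) stop("need >=2 samples", call. = FALSE)
  d <- ncol(x)

  rng <- apply(x, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1            # constant features scale to all-zero diffs
  xs <- sweep(sweep(x, 2L, rng[1L, ], `-`), 2L, span, `/`)
  xs[, rng[2L, ] - rng[1L, ] == 0] <- 0

  dm <- as.matrix(stats::dist(xs, method = "manhattan"))
  classes <- sort(unique(y))
  prior <- tabulate(y, max(classes)) / n

  idx <- if (is.null(sample_size) || sample_size >= n) {
    seq_len(n)
  } else {
    sort(sample.int(n, sample_size))
  }
  m <- length(idx)

  w <- numeric(d)
  for (i in idx) {
    di <- dm[i, ]
    for (c in classes) {
      members <- which(y == c)
      if (c == y[i]) members <- setdiff(members, i)
      if (length(members) == 0L) next
      kk <- min(k, length(members))
      nb <- members[order(di[members])][seq_len(kk)]
      diffs <- colMeans(abs(xs[nb, , drop = FALSE] -
                            matrix(xs[i, ], kk, d, byrow = TRUE)))
      if (c == y[i]) {
        w <- w - diffs / m
      } else {
        w <- w + (prior[c] / (1 - prior[y[i]])) * diffs / m
      }
    }
  }
  w
}

#' Absolute Pearson correlation of each feature with the class coding
#'
#' Correlates each feature with the integer-coded label; a zero-variance
#' feature is defined to score 0. Provided so the scorer ablation
#' (Relief-F vs correlation vs variance vs fusion) can be rerun.
#'
#' @inheritParams fisher_score
#' @return Numeric vector of scores in \[0,1\].
#' @export
pcc_score <- function(x, y) {
  x <- check_matrix(x)
  y <- as.numeric(as.integer(factor(y)))
  check_labels(y)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  xc <- sweep(x, 2L, colMeans(x), `-`)
  sx <- sqrt(colSums(xc^2))
  r <- abs(as.numeric(crossprod(xc, yc))) / (sx * sy)
  r[sx == 0] <- 0
  r
}

#' Sample variance of each feature
#'
#' Label-free total-variance scorer used by the scorer ablation.
#'
#' @inheritParams fisher_score
#' @return Numeric vector of per-feature sample variances.
#' @export
variance_score <- function(x) {
  x <- check_matrix(x)
  apply(x, 2L, stats::var)
}

#' Min-max rescale a score vector to \[0,1\]
#'
#' Relevance scorers live on incommensurate scales; fusion requires a common
#' one. An all-equal vector maps to all zeros.
#'
#' @param scores Finite numeric vector.
#' @return Numeric vector in \[0,1\].
#' @export
normalize_scores <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  rng <- range(scores)
  if (rng[2L] == rng[1L]) return(rep(0, length(scores)))
  (scores - rng[1L]) / (rng[2L] - rng[1L])
}

#' Fuse two score vectors by a weighted linear combination
#'
#' Combined weight of feature i is `alpha * a[i] + beta * b[i]`. The two
#' vectors are expected on a common scale (see [normalize_scores()]).
#'
#' @param a,b Score vectors of equal length.
#' @param alpha,beta Non-negative weights; `alpha + beta` must be positive.
#' @return Numeric vector of fused scores.
#' @export
fuse_scores <- function(a, b, alpha = 0.5, beta = 0.5) {
  if (length(a) != length(b)) stop("score vectors differ in length", call. = FALSE)
  if (alpha < 0 || beta < 0 || alpha + beta <= 0) {
    stop("weights must be non-negative with alpha + beta > 0", call. = FALSE)
  }
  alpha * a + beta * b
}

#' Score every feature of a labeled data frame
#'
#' Runs Relief-F and Fisher score, min-max normalizes each, and fuses them
#' into a single relevance score per feature. The returned table is sorted by
#' descending fused score (ranking ties broken by original column order).
#'
#' @param data Data frame, one row per sample.
#' @param label Label column (bare name or string).
#' @param alpha,beta Fusion weights for Relief-F and Fisher score.
#' @param relief_neighbors Neighbors per group for Relief-F.
#' @param relief_sample Instances sampled by Relief-F (`NULL` = all).
#' @return A tibble of class `feature_scores` with columns `feature`, `rank`,
#'   `relief`, `fisher` (normalized), `fused`.
#' @examples
#' ds <- make_synthetic_dataset(n_samples = 40, n_features = 30,
#'                              n_informative = 4, n_redundant = 2,
#'                              n_classes = 2, seed = 1)
#' score_features(ds$data, "class")
#' @export
score_features <- function(data, label = "class", alpha = 0.5, beta = 0.5,
                           relief_neighbors = 10, relief_sample = NULL) {
  ds <- split_labeled(data, {{ label }})
  log_row_access(data)
  rf <- normalize_scores(relief_score(ds$x, ds$y, k = relief_neighbors,
                                      sample_size = relief_sample))
  fs <- normalize_scores(fisher_score(ds$x, ds$y))
  fused <- fuse_scores(rf, fs, alpha, beta)
  ord <- order(-fused)            # radix sort: stable, ties keep column order
  out <- tibble::tibble(
    feature = ds$features[ord],
    rank = seq_along(fused),
    relief = rf[ord],
    fisher = fs[ord],
    fused = fused[ord]
  )
  attr(out, "feature_order") <- ds$features
  class(out) <- c("feature_scores", class(out))
  out
}
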