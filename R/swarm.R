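# Single-task competitive-swarm machinery: initialization, pairwise
# competition, the classical loser update, and elite-pool maintenance.
#
# A swarm is a plain list: pos and vel are pop_size x d matrices, fit/err are
# per-particle numerics (NA = unevaluated), mask is the task's logical
# candidate-dimension vector. Positions are clamped to [0,1], velocities to
# [-1,1], and non-candidate dimensions are pinned to exactly 0 so both tasks
# live in the same d-dimensional space.

#' Initialize a swarm for one task
#'
#' Positions are uniform on \[0,1\] in candidate dimensions and exactly 0
#' elsewhere; velocities start at 0 and fitness unevaluated. Consumes
#' `pop_size * d` uniform draws from the current RNG stream (row per
#' particle), regardless of the mask.
#'
#' @param task_mask Logical candidate-dimension vector, length d.
#' @param pop_size Number of particles, >= 2.
#' @return A swarm list (`pos`, `vel`, `fit`, `err`, `mask`).
#' @export
init_swarm <- function(task_mask, pop_size) {
  if (pop_size < 2L) stop("pop_size must be >= 2", call. = FALSE)
  d <- length(task_mask)
  pos <- matrix(stats::runif(pop_size * d), nrow = pop_size, ncol = d,
                byrow = TRUE)
  pos[, !task_mask] <- 0
  list(pos = pos,
       vel = matrix(0, pop_size, d),
       fit = rep(NA_real_, pop_size),
       err = rep(NA_real_, pop_size),
       mask = task_mask)
}

#' Randomly pair particles and declare winners
#'
#' Draws a uniformly random perfect matching (one particle is left over when
#' `pop_size` is odd and passes through the generation unchanged). Within a
#' pair the lower fitness wins; an exact tie goes to the lower particle index.
#'
#' @param swarm An evaluated swarm.
#' @return A list with `pairs` (two-column matrix, winner then loser) and
#'   `leftover` (index or `NA`).
#' @export
pair_particles <- function(swarm) {
  if (anyNA(swarm$fit)) stop("all particles must be evaluated before pairing",
                             call. = FALSE)
  n <- nrow(swarm$pos)
  perm <- sample.int(n)
  n_pairs <- n %/% 2L
  pairs <- matrix(NA_integer_, n_pairs, 2L,
                  dimnames = list(NULL, c("winner", "loser")))
  for (p in seq_len(n_pairs)) {
    a <- perm[2L * p - 1L]
    b <- perm[2L * p]
    better_a <- swarm$fit[a] < swarm$fit[b] ||
      (swarm$fit[a] == swarm$fit[b] && a < b)
    pairs[p, ] <- if (better_a) c(a, b) else c(b, a)
  }
  list(pairs = pairs, leftover = if (n %% 2L == 1L) perm[n] else NA_integer_)
}

#' Classical competitive-swarm loser update
#'
#' The loser learns from its pair's winner and the swarm centroid:
#' \deqn{V \leftarrow r_1 V + r_2 (X_W - X) + \varphi r_3 (\bar X - X)}
#' \deqn{X \leftarrow X + V}
#' with \eqn{r_1, r_2, r_3} uniform \[0,1\] drawn per dimension. The velocity
#' is then clamped to \[-1,1\], the position to \[0,1\], and non-candidate
#' dimensions re-zeroed. Winners (and an odd-size leftover) are never updated.
#'
#' @param position,velocity Loser state, numeric length d.
#' @param winner_position Winner position.
#' @param mean_position Swarm mean position at the start of the generation.
#' @param task_mask Candidate-dimension mask.
#' @param phi Centroid-pull weight, >= 0.
#' @param r Optional list(r1, r2, r3) overriding the random coefficients
#'   (testing hook); by default three length-d uniform vectors are drawn, in
#'   the order r1, r2, r3.
#' @return list(position, velocity) after the update.
#' @export
classical_loser_update <- function(position, velocity, winner_position,
                                   mean_position, task_mask = NULL,
                                   phi = 0.1, r = NULL) {
  d <- length(position)
  if (length(velocity) != d || length(winner_position) != d ||
      length(mean_position) != d) {
    stop("vector lengths differ", call. = FALSE)
  }
  if (is.null(task_mask)) task_mask <- rep(TRUE, d)
  if (is.null(r)) r <- list(r1 = stats::runif(d), r2 = stats::runif(d),
                            r3 = stats::runif(d))
  v <- r$r1 * velocity + r$r2 * (winner_position - position) +
    phi * r$r3 * (mean_position - position)
  v <- clamp(v, -1, 1)
  x <- clamp(position + v, 0, 1)
  x[!task_mask] <- 0
  list(position = x, velocity = v)
}

#' Select the elite pool of a swarm
#'
#' The `k_elite` lowest-fitness particles (ties broken by particle index),
#' copied out of the swarm together with their mean position. `k_elite` is
#' clamped to the population size.
#'
#' @param swarm An evaluated swarm.
#' @param k_elite Pool size, >= 1.
#' @return list(indices, pos (k x d matrix), fit, mean) of class `elite_pool`.
#' @export
select_elites <- function(swarm, k_elite) {
  if (k_elite < 1L) stop("k_elite must be >= 1", call. = FALSE)
  if (anyNA(swarm$fit)) stop("all particles must be evaluated", call. = FALSE)
  n <- nrow(swarm$pos)
  k <- min(k_elite, n)
  ord <- order(swarm$fit, seq_len(n))[seq_len(k)]
  res <- list(indices = ord,
              pos = swarm$pos[ord, , drop = FALSE],
              fit = swarm$fit[ord],
              mean = colMeans(swarm$pos[ord, , drop = FALSE]))
  class(res) <- "elite_pool"
  res
}
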