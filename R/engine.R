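# Dual-task engine: four-mode loser updates, cross-task elite transfer, and
# the main optimization loop, plus the ablation variants.
#
# Reproducibility contract (the fixed RNG draw order, so seeded runs are
# exactly repeatable):
#   run start : set.seed(seed) -> inner CV fold assignment -> task
#               construction (no draws with full Relief-F sampling) -> swarm
#               initialization, task 1 then task 2.
#   generation: pairing permutation for task 1, then task 2; then losers are
#               updated task 1 first, pair by pair in matching order.
#   per loser : 2 mode uniforms (always drawn, whatever the probabilities),
#               then r1, r2, r3 (length-d uniform vectors, in that order),
#               then any source-selection draw (own elite index, then
#               other-task elite index or other-task winner index).

#' Draw the update mode for one loser
#'
#' Two independent uniforms decide (i) whether the loser learns across tasks
#' (`u1 < p_trans`) and (ii) whether it learns from an elite rather than a
#' winner/centroid source (`u2 < p_k`), giving the four update modes.
#'
#' @param p_trans Cross-task transfer probability in \[0,1\].
#' @param p_k Elite-learning probability in \[0,1\].
#' @return list(cross, elite) of logicals.
#' @export
choose_update_mode <- function(p_trans, p_k) {
  u <- stats::runif(2L)
  list(cross = u[1L] < p_trans, elite = u[2L] < p_k)
}

#' Four-mode loser update with optional cross-task elite transfer
#'
#' Applies one of the four velocity rules depending on `mode`
#' (all with per-dimension uniform coefficients r1, r2, r3):
#' \itemize{
#'   \item cross & elite: \eqn{V \gets r_1 V + r_2 (X_E^{own} - X) + r_3 (X_E^{other} - X)}
#'     with uniformly drawn members of the own and other elite pools;
#'   \item cross & !elite: \eqn{V \gets r_1 V + r_2 (X_W - X) + r_3 (X_W^{other} - X)}
#'     with a uniformly drawn winner of the other task;
#'   \item !cross & elite: \eqn{V \gets r_1 V + r_2 (X_E^{own} - X) + \varphi r_3 (\bar X_E^{own} - X)};
#'   \item !cross & !elite: the classical update
#'     \eqn{V \gets r_1 V + r_2 (X_W - X) + \varphi r_3 (\bar X - X)}.
#' }
#' Then \eqn{X \gets X + V}, with the usual clamps and re-zeroing of the
#' loser's non-candidate dimensions.
#'
#' @param position,velocity Loser state.
#' @param mode list(cross, elite) from [choose_update_mode()].
#' @param winner_position The loser's own pair winner.
#' @param own_elites,other_elites `elite_pool` objects ('other' may be `NULL`
#'   when `mode$cross` is `FALSE`).
#' @param other_winners Matrix of the other task's current winner positions.
#' @param swarm_mean Own swarm mean position.
#' @param task_mask Candidate mask of the loser's task.
#' @param phi Centroid/elite-mean pull weight.
#' @param r Optional list(r1, r2, r3) testing hook.
#' @return list(position, velocity).
#' @export
transfer_update <- function(position, velocity, mode, winner_position,
                            own_elites, other_elites = NULL,
                            other_winners = NULL, swarm_mean,
                            task_mask = NULL, phi = 0.1, r = NULL) {
  d <- length(position)
  if (is.null(task_mask)) task_mask <- rep(TRUE, d)
  if (is.null(r)) r <- list(r1 = stats::runif(d), r2 = stats::runif(d),
                            r3 = stats::runif(d))
  if (mode$elite) {
    if (is.null(own_elites) || nrow(own_elites$pos) == 0L) {
      stop("elite pool required", call. = FALSE)
    }
    own_src <- own_elites$pos[sample.int(nrow(own_elites$pos), 1L), ]
  } else {
    own_src <- winner_position
  }
  if (mode$cross) {
    if (mode$elite) {
      if (is.null(other_elites) || nrow(other_elites$pos) == 0L) {
        stop("elite pool required", call. = FALSE)
      }
      other_src <- other_elites$pos[sample.int(nrow(other_elites$pos), 1L), ]
    } else {
      if (is.null(other_winners) || nrow(other_winners) == 0L) {
        stop("other-task winners required", call. = FALSE)
      }
      other_src <- other_winners[sample.int(nrow(other_winners), 1L), ]
    }
    v <- r$r1 * velocity + r$r2 * (own_src - position) +
      r$r3 * (other_src - position)
  } else {
    pull <- if (mode$elite) own_elites$mean else swarm_mean
    v <- r$r1 * velocity + r$r2 * (own_src - position) +
      phi * r$r3 * (pull - position)
  }
  v <- clamp(v, -1, 1)
  x <- clamp(position + v, 0, 1)
  x[!task_mask] <- 0
  list(position = x, velocity = v)
}

#' Dual-task competitive-swarm feature selection
#'
#' Runs the full method: fused Relief-F + Fisher scoring with knee-point
#' thresholding builds a compact auxiliary task next to the full-space
#' primary task; each task evolves a competitive swarm whose losers learn
#' from pair winners, hierarchical elite pools, and (with probability
#' `p_trans`) the elites/winners of the other task; subsets are scored by the
#' balanced-error + sparsity wrapper fitness under inner cross-validation.
#'
#' @inheritParams score_features
#' @param variant `"multitask"` (the full method), `"no_transfer"` (two tasks,
#'   elite competition, no cross-task exchange), or `"cso"` (single full-space
#'   task, classical competitive swarm only).
#' @param pop_size Particles per task (default 70).
#' @param max_iter Generations (default 100); 0 returns the best initial
#'   particle.
#' @param p_trans,p_k Transfer and elite-learning probabilities (default 0.6).
#' @param phi Centroid-pull weight (default 0.1).
#' @param k_elite Elite-pool size (default `ceiling(0.1 * pop_size)`).
#' @param decode_threshold Position-to-mask decode threshold (default 0.6).
#' @param alpha_f Accuracy/sparsity trade-off (default 0.999999).
#' @param inner_folds Inner CV folds for the wrapper fitness (default 5).
#' @param classifier `"nn1"` or a `list(fit =, predict =)` plug-in.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @param fitness_fun Optional replacement objective
#'   `function(selected_logical) -> numeric` (used for algorithmic tests);
#'   when supplied no data-driven fitness is built.
#' @param trace Keep per-generation copies of every swarm state (memory-heavy;
#'   for equivalence testing).
#' @return An object of class `swarm_select`; see [tidy.swarm_select()],
#'   [glance.swarm_select()] and [autoplot.swarm_select()].
#' @examples
#' ds <- make_synthetic_dataset(n_samples = 60, n_features = 80,
#'                              n_informative = 5, n_redundant = 5,
#'                              n_classes = 2, seed = 1)
#' fit <- swarm_select(ds$data, "class", pop_size = 10, max_iter = 5, seed = 1)
#' glance(fit)
#' @export
swarm_select <- function(data, label = "class",
                         variant = c("multitask", "no_transfer", "cso"),
                         pop_size = 70, max_iter = 100,
                         p_trans = 0.6, p_k = 0.6, phi = 0.1,
                         k_elite = ceiling(0.1 * pop_size),
                         decode_threshold = 0.6, alpha_f = 0.999999,
                         inner_folds = 5, classifier = "nn1",
                         alpha = 0.5, beta = 0.5, relief_neighbors = 10,
                         seed = NULL, fitness_fun = NULL, trace = FALSE) {
  variant <- match.arg(variant)
  ds <- split_labeled(data, {{ label }})
  log_row_access(data)
  check_labels(ds$y)
  if (!is.null(seed)) set.seed(seed)

  eval_fun <- if (is.null(fitness_fun)) {
    make_subset_evaluator(ds$x, ds$y, inner_folds = inner_folds,
                          alpha_f = alpha_f, classifier = classifier)
  } else {
    function(sel) c(fitness = fitness_fun(sel), error = NA_real_)
  }

  d <- length(ds$features)
  if (variant == "cso") {
    masks <- list(primary = stats::setNames(rep(TRUE, d), ds$features))
    task_pair <- NULL
    p_trans <- 0
    p_k <- 0
  } else {
    task_pair <- build_tasks(data, {{ label }}, alpha = alpha, beta = beta,
                             relief_neighbors = relief_neighbors)
    masks <- list(primary = task_pair$primary_mask,
                  auxiliary = task_pair$auxiliary_mask)
    if (variant == "no_transfer") p_trans <- 0
  }

  res <- run_engine(masks, eval_fun, pop_size = pop_size, max_iter = max_iter,
                    p_trans = p_trans, p_k = p_k, phi = phi,
                    k_elite = k_elite, decode_threshold = decode_threshold,
                    trace = trace)

  out <- list(
    best_mask = stats::setNames(res$best_mask, ds$features),
    best_fitness = res$best_fitness,
    best_error = res$best_error,
    best_task = names(masks)[res$best_task],
    selected_features = ds$features[res$best_mask],
    history = res$history,
    n_cross_reads = res$n_cross_reads,
    task_pair = task_pair,
    variant = variant,
    n_features = d,
    config = list(pop_size = pop_size, max_iter = max_iter, p_trans = p_trans,
                  p_k = p_k, phi = phi, k_elite = k_elite,
                  decode_threshold = decode_threshold, alpha_f = alpha_f,
                  inner_folds = inner_folds, alpha = alpha, beta = beta,
                  relief_neighbors = relief_neighbors),
    seed = seed,
    trace = res$trace
  )
  class(out) <- "swarm_select"
  out
}

# Core loop over an arbitrary list of task masks. eval_fun maps a logical
# selection to c(fitness, error). Returns raw (unnamed) results.
run_engine <- function(masks, eval_fun, pop_size, max_iter, p_trans, p_k,
                       phi, k_elite, decode_threshold, trace = FALSE) {
  n_tasks <- length(masks)
  d <- length(masks[[1L]])
  swarms <- lapply(masks, init_swarm, pop_size = pop_size)
  n_cross_reads <- 0L

  evaluate_swarm <- function(sw) {
    todo <- which(is.na(sw$fit))
    for (i in todo) {
      sel <- decode_mask(sw$pos[i, ], sw$mask, decode_threshold)
      val <- eval_fun(sel)
      sw$fit[i] <- val[[1L]]
      sw$err[i] <- val[[2L]]
    }
    sw
  }

  best <- list(fitness = Inf, error = NA_real_, mask = NULL, task = NA_integer_)
  history <- vector("list", 0L)
  trace_log <- if (trace) vector("list", max_iter + 1L) else NULL

  record <- function(gen) {
    for (t in seq_len(n_tasks)) {
      sw <- swarms[[t]]
      b <- which.min(sw$fit)     # first minimum: lowest index on ties
      if (sw$fit[b] < best$fitness) {
        best <<- list(fitness = sw$fit[b], error = sw$err[b],
                      mask = decode_mask(sw$pos[b, ], sw$mask, decode_threshold),
                      task = t)
      }
      sel_n <- sum(decode_mask(sw$pos[b, ], sw$mask, decode_threshold))
      history[[length(history) + 1L]] <<- tibble::tibble(
        generation = gen, task = names(masks)[t],
        best_fitness = sw$fit[b], mean_fitness = mean(sw$fit),
        best_subset_size = sel_n)
    }
    if (trace) trace_log[[gen + 1L]] <<- lapply(swarms, function(s)
      list(pos = s$pos, vel = s$vel, fit = s$fit))
  }

  swarms <- lapply(swarms, evaluate_swarm)
  record(0L)

  if (max_iter > 0) for (gen in seq_len(max_iter)) {
    snap <- lapply(swarms, function(s)
      list(pos = s$pos, mean = colMeans(s$pos)))
    elites <- lapply(swarms, select_elites, k_elite = k_elite)
    matchings <- lapply(seq_len(n_tasks), function(t)
      pair_particles(swarms[[t]]))
    winners <- lapply(seq_len(n_tasks), function(t)
      snap[[t]]$pos[matchings[[t]]$pairs[, "winner"], , drop = FALSE])

    for (t in seq_len(n_tasks)) {
      other <- if (n_tasks == 2L) 3L - t else NA_integer_
      pairs <- matchings[[t]]$pairs
      for (p in seq_len(nrow(pairs))) {
        w <- pairs[p, "winner"]
        l <- pairs[p, "loser"]
        mode <- choose_update_mode(p_trans, p_k)
        if (mode$cross) n_cross_reads <- n_cross_reads + 1L
        upd <- transfer_update(
          position = swarms[[t]]$pos[l, ],
          velocity = swarms[[t]]$vel[l, ],
          mode = mode,
          winner_position = snap[[t]]$pos[w, ],
          own_elites = elites[[t]],
          other_elites = if (mode$cross) elites[[other]] else NULL,
          other_winners = if (mode$cross) winners[[other]] else NULL,
          swarm_mean = snap[[t]]$mean,
          task_mask = swarms[[t]]$mask,
          phi = phi)
        swarms[[t]]$pos[l, ] <- upd$position
        swarms[[t]]$vel[l, ] <- upd$velocity
        swarms[[t]]$fit[l] <- NA_real_
        swarms[[t]]$err[l] <- NA_real_
      }
    }
    swarms <- lapply(swarms, evaluate_swarm)
    record(gen)
  }

  list(best_fitness = best$fitness, best_error = best$error,
       best_mask = best$mask, best_task = best$task,
       history = dplyr::bind_rows(history),
       n_cross_reads = n_cross_reads, trace = trace_log)
}
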