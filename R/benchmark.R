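# Outer evaluation protocol: per-fold feature selection, repeated runs, and
# Wilcoxon signed-rank comparisons between methods.

#' Outer cross-validated benchmark of a selection variant
#'
#' Implements the unbiased protocol: for each outer stratified fold, feature
#' selection (task construction, swarm search, wrapper fitness) runs on the
#' training partition only; the classifier is then fit on the training rows
#' restricted to the selected features and scored on the held-out fold. The
#' whole procedure is repeated `n_runs` times with run seeds
#' `base_seed + run - 1`. Reported accuracy is balanced accuracy
#' `100 * (1 - balanced error)`; plain accuracy is reported alongside.
#'
#' @inheritParams swarm_select
#' @param variant A [swarm_select()] variant, or `"none"` for the
#'   no-selection baseline (all features).
#' @param outer_folds Outer stratified folds (default 10; reduced with a
#'   warning when a class is smaller).
#' @param n_runs Independent repetitions (default 30).
#' @param base_seed Seed of the first run.
#' @param ... Further arguments passed to [swarm_select()].
#' @return An object of class `fs_benchmark` with per-run results; see
#'   [tidy.fs_benchmark()] / [glance.fs_benchmark()].
#' @export
evaluate_benchmark <- function(data, label = "class", variant = "multitask",
                               outer_folds = 10, n_runs = 30, base_seed = 1,
                               ...) {
  label <- resolve_label(data, {{ label }})
  ds <- split_labeled(data, label)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed <- base_seed + r - 1L
    set.seed(seed)
    fold <- make_folds(ds$y, outer_folds)
    accs <- plain <- sizes <- numeric(max(fold))
    for (f in seq_len(max(fold))) {
      te <- fold == f
      train <- data[!te, , drop = FALSE]
      attr(train, "swarmsel_row_ids") <- which(!te)
      log_env <- getOption("swarmsel.access_log", NULL)
      if (!is.null(log_env)) log_env$held_out <- which(te)
      sel <- if (identical(variant, "none")) {
        rep(TRUE, length(ds$features))
      } else {
        fit <- swarm_select(train, label, variant = variant, seed = NULL, ...)
        fit$best_mask
      }
      if (!is.null(log_env)) log_env$held_out <- integer(0)  # scoring may touch them
      if (!any(sel)) sel <- rep(TRUE, length(ds$features))
      pred <- nn1_predict(ds$x[!te, sel, drop = FALSE], ds$y[!te],
                          ds$x[te, sel, drop = FALSE])
      bm <- balanced_error(ds$y[te], pred)
      accs[f] <- 100 * (1 - bm$balanced_error)
      plain[f] <- 100 * mean(pred == ds$y[te])
      sizes[f] <- sum(sel)
    }
    runs[[r]] <- tibble::tibble(run = r, seed = seed,
                                accuracy = mean(accs),
                                plain_accuracy = mean(plain),
                                subset_size = mean(sizes))
  }
  res <- list(runs = dplyr::bind_rows(runs), variant = variant,
              outer_folds = outer_folds, n_runs = n_runs,
              base_seed = base_seed, n_features = length(ds$features))
  class(res) <- "fs_benchmark"
  res
}

#' @export
print.fs_benchmark <- function(x, ...) {
  g <- glance(x)
  cat("Benchmark of '", x$variant, "': ", x$n_runs, " run(s) x ",
      x$outer_folds, "-fold outer CV\n", sep = "")
  cat(sprintf("  balanced accuracy: %.2f%% (sd %.2f)\n",
              g$mean_accuracy, g$sd_accuracy))
  cat(sprintf("  mean subset size : %.1f of %d\n",
              g$mean_subset_size, x$n_features))
  invisible(x)
}

#' Per-run benchmark results
#'
#' @param x An `fs_benchmark`.
#' @param ... Unused.
#' @return Tibble with one row per run: `run`, `seed`, `accuracy` (balanced,
#'   %), `plain_accuracy`, `subset_size`.
#' @export
tidy.fs_benchmark <- function(x, ...) x$runs

#' One-row benchmark summary
#'
#' @param x An `fs_benchmark`.
#' @param ... Unused.
#' @return Tibble: `variant`, `n_runs`, means and SDs of accuracy and subset
#'   size.
#' @export
glance.fs_benchmark <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_runs = x$n_runs,
    mean_accuracy = mean(x$runs$accuracy),
    sd_accuracy = stats::sd(x$runs$accuracy),
    mean_plain_accuracy = mean(x$runs$plain_accuracy),
    mean_subset_size = mean(x$runs$subset_size),
    sd_subset_size = stats::sd(x$runs$subset_size)
  )
}

#' Wilcoxon signed-rank comparison of two benchmark reports
#'
#' Pairs the per-run values of a metric across two reports and applies the
#' Wilcoxon signed-rank test at `alpha`. The call follows the benchmarking
#' convention: `"+"` means `x` is significantly better than `y`, `"-"`
#' significantly worse, `"="` no significant difference. For accuracy higher
#' is better; for `subset_size` lower is better.
#'
#' @param x,y `fs_benchmark` objects with equal `n_runs`.
#' @param metric `"accuracy"`, `"plain_accuracy"` or `"subset_size"`.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: variants, metric means, `p_value`, `call`.
#' @export
compare_runs <- function(x, y, metric = "accuracy", alpha = 0.05) {
  a <- tidy(x)[[metric]]
  b <- tidy(y)[[metric]]
  if (length(a) != length(b)) stop("reports have unpaired run counts",
                                   call. = FALSE)
  if (all(a == b)) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE)$p.value)
  }
  higher_better <- metric != "subset_size"
  call <- if (p >= alpha) {
    "="
  } else if ((mean(a) > mean(b)) == higher_better) {
    "+"
  } else {
    "-"
  }
  tibble::tibble(variant_x = x$variant, variant_y = y$variant,
                 metric = metric, mean_x = mean(a), mean_y = mean(b),
                 p_value = p, call = call)
}
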