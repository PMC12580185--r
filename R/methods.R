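# broom-style methods and plots for fitted selection objects.

#' @export
print.swarm_select <- function(x, ...) {
  cat("Dual-task swarm feature selection (variant: ", x$variant, ")\n", sep = "")
  cat("  features : ", sum(x$best_mask), " of ", x$n_features, " selected\n",
      sep = "")
  cat("  fitness  : ", format(x$best_fitness, digits = 8),
      if (!is.na(x$best_error))
        paste0(" (balanced error ", format(x$best_error, digits = 4), ")"),
      "\n", sep = "")
  cat("  best task: ", x$best_task, "; generations: ", x$config$max_iter,
      "; population: ", x$config$pop_size, "\n", sep = "")
  invisible(x)
}

#' Per-feature table of a selection fit
#'
#' One row per feature with its selection flag and, when the dual tasks were
#' built, its fused relevance rank and auxiliary-task membership.
#'
#' @param x A `swarm_select` object.
#' @param ... Unused.
#' @return A tibble: `feature`, `selected`, and (for dual-task variants)
#'   `rank`, `fused`, `in_auxiliary`.
#' @export
tidy.swarm_select <- function(x, ...) {
  out <- tibble::tibble(feature = names(x$best_mask),
                        selected = unname(x$best_mask))
  if (!is.null(x$task_pair)) {
    out <- dplyr::left_join(out, x$task_pair$scores[, c("feature", "rank",
                                                        "fused", "in_auxiliary")],
                            by = "feature")
  }
  out
}

#' One-row summary of a selection fit
#'
#' @param x A `swarm_select` object.
#' @param ... Unused.
#' @return A tibble: `variant`, `best_fitness`, `balanced_error`,
#'   `n_selected`, `selected_fraction`, `n_features`, `best_task`,
#'   `generations`.
#' @export
glance.swarm_select <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    best_fitness = x$best_fitness,
    balanced_error = x$best_error,
    n_selected = sum(x$best_mask),
    selected_fraction = sum(x$best_mask) / x$n_features,
    n_features = x$n_features,
    best_task = x$best_task,
    generations = x$config$max_iter
  )
}

#' Convergence plot of a selection fit
#'
#' @param object A `swarm_select` object.
#' @param ... Unused.
#' @return A ggplot of per-task best fitness across generations.
#' @export
autoplot.swarm_select <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation, y = .data$best_fitness,
                               colour = .data$task)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best fitness (lower is better)",
                  colour = "task",
                  title = "Swarm convergence by task") +
    ggplot2::theme_minimal()
}
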