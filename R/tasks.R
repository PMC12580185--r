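# Dual-task construction: full feature space + knee-selected subspace.

#' Build the dual search tasks from fused feature scores
#'
#' Scores every feature ([score_features()]), detects the knee of the ranked
#' fused-score curve ([detect_knee()]), and returns the two search tasks: the
#' primary task keeps the full feature set while the auxiliary task is
#' restricted to the features ranked at or above the knee.
#'
#' @inheritParams score_features
#' @return An object of class `task_pair`: a list with `scores` (the
#'   `feature_scores` tibble with an `in_auxiliary` column), `knee`
#'   (a `knee_result`), `primary_mask` and `auxiliary_mask` (named logicals
#'   over the original feature order), and `features`.
#' @examples
#' ds <- make_synthetic_dataset(n_samples = 40, n_features = 30,
#'                              n_informative = 4, n_redundant = 2,
#'                              n_classes = 2, seed = 1)
#' tp <- build_tasks(ds$data, "class")
#' sum(tp$auxiliary_mask)
#' @export
build_tasks <- function(data, label = "class", alpha = 0.5, beta = 0.5,
                        relief_neighbors = 10, relief_sample = NULL) {
  sc <- score_features(data, {{ label }}, alpha = alpha, beta = beta,
                       relief_neighbors = relief_neighbors,
                       relief_sample = relief_sample)
  knee <- detect_knee(sc$fused)
  sc$in_auxiliary <- sc$rank <= knee$selected_count
  features <- sort_features_original(sc)
  aux <- stats::setNames(logical(length(features)), features)
  aux[sc$feature[sc$in_auxiliary]] <- TRUE
  res <- list(
    scores = sc,
    knee = knee,
    primary_mask = stats::setNames(rep(TRUE, length(features)), features),
    auxiliary_mask = aux,
    features = features
  )
  class(res) <- "task_pair"
  res
}

# Recover the original column order of the scored features.
sort_features_original <- function(sc) {
  attr_order <- attr(sc, "feature_order")
  if (!is.null(attr_order)) return(attr_order)
  sc$feature                      # ranked order; only hit for hand-built tables
}

#' @export
print.task_pair <- function(x, ...) {
  cat("Dual feature-selection tasks over", length(x$features), "features\n")
  cat("  primary  : full feature set\n")
  cat("  auxiliary:", sum(x$auxiliary_mask), "features at/above the knee (rank",
      x$knee$knee_index, ")\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a task pair into its per-feature score table
#'
#' @param x A `task_pair`.
#' @param ... Unused.
#' @return The `feature_scores` tibble with the `in_auxiliary` flag.
#' @export
tidy.task_pair <- function(x, ...) x$scores

#' Ranked score curve with the knee highlighted
#'
#' @param object A `task_pair` from [build_tasks()].
#' @param ... Unused.
#' @return A ggplot of fused score against rank, with the knee point and the
#'   chord used to find it.
#' @export
autoplot.task_pair <- function(object, ...) {
  sc <- object$scores
  knee <- object$knee
  chord <- tibble::tibble(rank = c(1, nrow(sc)),
                          fused = c(sc$fused[1L], sc$fused[nrow(sc)]))
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$rank, y = .data$fused)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_line(data = chord, linetype = "dashed", colour = "grey50") +
    ggplot2::annotate("point", x = knee$knee_index, y = knee$threshold_score,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "feature rank", y = "fused relevance score",
                  title = "Ranked score curve and knee point") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
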