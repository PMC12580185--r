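# Subset decoding and the balanced-error + sparsity wrapper fitness.

#' Decode a continuous particle position into a feature mask
#'
#' A dimension is selected when its position exceeds `threshold` AND it is a
#' candidate dimension of the particle's task.
#'
#' @param position Numeric vector in \[0,1\] per dimension.
#' @param task_mask Logical candidate mask of the same length (default: all).
#' @param threshold Decode threshold in (0,1).
#' @return Logical selection vector.
#' @export
decode_mask <- function(position, task_mask = NULL, threshold = 0.6) {
  if (is.null(task_mask)) task_mask <- rep(TRUE, length(position))
  if (length(task_mask) != length(position)) {
    stop("position and task_mask differ in length", call. = FALSE)
  }
  (position > threshold) & task_mask
}

#' Balanced error rate from true and predicted labels
#'
#' Per-class true-positive rates are averaged so every class contributes
#' equally regardless of its size: \deqn{\gamma = 1 - \frac{1}{C}\sum_i TPR_i.}
#' Every class level must be present in `truth` (otherwise its TPR is
#' undefined).
#'
#' @param truth,estimate Equal-length label vectors (factors or coercible).
#' @param levels Optional explicit class levels; defaults to the levels found
#'   in `truth`.
#' @return A list of class `class_metrics`: `tpr_per_class`, `balanced_error`,
#'   `n_classes`.
#' @examples
#' balanced_error(c(0, 0, 1, 1), c(0, 0, 1, 0))
#' @export
balanced_error <- function(truth, estimate, levels = NULL) {
  if (length(truth) != length(estimate)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (is.null(levels)) levels <- sort(unique(as.character(truth)))
  tf <- factor(as.character(truth), levels = levels)
  ef <- factor(as.character(estimate), levels = levels)
  sizes <- table(tf)
  if (any(sizes == 0L)) {
    stop("class '", names(sizes)[sizes == 0L][1L],
         "' absent from truth; TPR undefined", call. = FALSE)
  }
  correct <- tapply(ef == tf, tf, sum)
  tpr <- as.numeric(correct) / as.numeric(sizes)
  res <- list(tpr_per_class = stats::setNames(tpr, levels),
              balanced_error = 1 - mean(tpr),
              n_classes = length(levels))
  class(res) <- "class_metrics"
  res
}

#' Combine a classification error and a subset size into the scalar fitness
#'
#' \deqn{fitness = \alpha_f \gamma + (1 - \alpha_f) |S| / |N|} with
#' \eqn{\gamma} the balanced error, \eqn{|S|} the number of selected features
#' and \eqn{|N|} the total number of features. `alpha_f` close to 1 makes the
#' sparsity term a tie-breaker among equally accurate subsets. Lower is
#' better; the empty subset is assigned the worst value 1.
#'
#' @param error Balanced error in \[0,1\].
#' @param n_selected,n_features Subset and universe sizes.
#' @param alpha_f Accuracy/sparsity trade-off in (0,1); default 0.999999.
#' @return Scalar fitness in \[0,1\].
#' @export
fitness_score <- function(error, n_selected, n_features, alpha_f = 0.999999) {
  if (n_selected == 0L) return(1)
  alpha_f * error + (1 - alpha_f) * n_selected / n_features
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into folds. Folds are reduced (with a warning) when a class is
# smaller than the requested count.
make_folds <- function(y, n_folds) {
  smallest <- min(table(y))
  if (n_folds > smallest) {
    warning("reducing folds from ", n_folds, " to smallest class size ",
            smallest, call. = FALSE)
    n_folds <- max(2L, smallest)
  }
  fold <- integer(length(y))
  for (c in unique(y)) {
    idx <- which(y == c)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Deterministic 1-nearest-neighbor prediction: z-scores columns with
# training statistics (a zero-variance training column is dropped from the
# distance), then takes the argmin of squared Euclidean cross-distances with
# first-index tie-breaking.
nn1_predict <- function(train_x, train_y, test_x) {
  mu <- colMeans(train_x)
  sd <- sqrt(colMeans(train_x * train_x) - mu * mu)
  w <- ifelse(sd > 0, 1 / sd, 0)
  tr <- sweep(sweep(train_x, 2L, mu, `-`), 2L, w, `*`)
  te <- sweep(sweep(test_x, 2L, mu, `-`), 2L, w, `*`)
  d2 <- outer(rowSums(te * te), rowSums(tr * tr), `+`) - 2 * tcrossprod(te, tr)
  train_y[max.col(-d2, ties.method = "first")]
}

# Evaluator factory: fixes the inner CV folds once (consuming the current RNG
# stream) and returns a memoized function(selected) -> c(fitness, error).
# A plug-in classifier is a list(fit = function(x, y), predict =
# function(model, x)); the string "nn1" selects the fast built-in path.
make_subset_evaluator <- function(x, y, inner_folds = 5, alpha_f = 0.999999,
                                  classifier = "nn1") {
  n <- nrow(x)
  d <- ncol(x)
  fold <- make_folds(y, inner_folds)
  n_folds <- max(fold)
  levels <- sort(unique(y))
  cache <- new.env(parent = emptyenv())

  eval_uncached <- function(sel) {
    idx <- which(sel)
    errs <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      te <- fold == f
      trx <- x[!te, idx, drop = FALSE]
      tex <- x[te, idx, drop = FALSE]
      pred <- if (identical(classifier, "nn1")) {
        nn1_predict(trx, y[!te], tex)
      } else {
        model <- classifier$fit(trx, y[!te])
        classifier$predict(model, tex)
      }
      errs[f] <- balanced_error(y[te], pred, levels = levels)$balanced_error
    }
    gamma <- mean(errs)
    c(fitness = fitness_score(gamma, length(idx), d, alpha_f), error = gamma)
  }

  function(sel) {
    if (!any(sel)) return(c(fitness = 1, error = NA_real_))
    key <- paste(which(sel), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- eval_uncached(sel)
    cache[[key]] <- val
    val
  }
}

#' Evaluate one feature subset under the wrapper fitness
#'
#' Scores a fixed feature subset by stratified inner cross-validation with the
#' plug-in classifier (default: the built-in deterministic 1-nearest-neighbor
#' on z-scored features), then combines the mean balanced error with the
#' sparsity term via [fitness_score()].
#'
#' @inheritParams score_features
#' @param selected Logical vector over the feature columns, or a character
#'   vector of feature names.
#' @param inner_folds Cross-validation folds (reduced with a warning when a
#'   class is smaller).
#' @param alpha_f Accuracy/sparsity trade-off.
#' @param classifier `"nn1"` or a `list(fit =, predict =)` plug-in.
#' @param seed Optional seed for the fold assignment.
#' @return One-row tibble: `fitness`, `balanced_error`, `n_selected`,
#'   `n_features`.
#' @export
evaluate_subset <- function(data, label = "class", selected,
                            inner_folds = 5, alpha_f = 0.999999,
                            classifier = "nn1", seed = NULL) {
  ds <- split_labeled(data, {{ label }})
  log_row_access(data)
  if (is.character(selected)) selected <- ds$features %in% selected
  if (length(selected) != length(ds$features)) {
    stop("selection length does not match the number of features", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ev <- make_subset_evaluator(ds$x, ds$y, inner_folds = inner_folds,
                              alpha_f = alpha_f, classifier = classifier)
  val <- ev(selected)
  tibble::tibble(fitness = val[["fitness"]],
                 balanced_error = val[["error"]],
                 n_selected = sum(selected),
                 n_features = length(selected))
}
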