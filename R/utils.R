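# Shared input checking and label handling.

#' Split a labeled data frame into a numeric matrix and coded labels
#'
#' @param data A data frame, one row per sample.
#' @param label Column name (string or bare name) holding the class label.
#' @return list(x = numeric matrix n x d, y = integer codes 1..C,
#'   classes = class levels, features = feature names)
#' @noRd
split_labeled <- function(data, label) {
  label <- tryCatch(resolve_label(data, {{ label }}), error = function(e) {
    stop("label column not found in data: ", conditionMessage(e), call. = FALSE)
  })
  feats <- setdiff(names(data), label)
  if (length(feats) == 0L) stop("no feature columns in data", call. = FALSE)
  xdf <- data[feats]
  bad <- names(xdf)[!vapply(xdf, is.numeric, logical(1))]
  if (length(bad) > 0L) {
    stop("non-numeric feature column(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(xdf)
  if (anyNA(x) || any(!is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite value at row ", idx[1L], ", column '", feats[idx[2L]], "'",
         call. = FALSE)
  }
  yf <- factor(data[[label]])
  list(x = x, y = as.integer(yf), classes = levels(yf), features = feats,
       label = label)
}

# Accept a string, a bare column name, or a variable holding either.
resolve_label <- function(data, label) {
  tidyselect::vars_pull(names(data), {{ label }})
}

check_labels <- function(y) {
  if (length(unique(y)) < 2L) stop("need >=2 classes", call. = FALSE)
  invisible(y)
}

check_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("feature matrix must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("feature matrix contains non-finite entries", call. = FALSE)
  x
}

clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# Leak detector: when the option `swarmsel.access_log` is set to an
# environment, every selection-stage entry point records the original row ids
# it received (the "swarmsel_row_ids" attribute the benchmark harness attaches
# to each training partition). The harness publishes the currently held-out
# rows in env$held_out; any overlap is counted as a violation.
log_row_access <- function(data_or_ids) {
  env <- getOption("swarmsel.access_log", NULL)
  if (is.null(env)) return(invisible(NULL))
  ids <- if (is.data.frame(data_or_ids)) {
    attr(data_or_ids, "swarmsel_row_ids")
  } else {
    data_or_ids
  }
  if (is.null(ids)) return(invisible(NULL))
  env$n_calls <- (env$n_calls %||% 0L) + 1L
  env$violations <- (env$violations %||% 0L) +
    length(intersect(ids, env$held_out))
  invisible(NULL)
}
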