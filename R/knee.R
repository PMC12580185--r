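# Knee-point detection on a ranked score curve.

#' Find the knee of a descending score curve
#'
#' Draws the chord from the first point `(1, s[1])` to the last
#' `(d, s[d])` of the ranked score curve and returns the point at maximum
#' perpendicular distance from it. Used as an adaptive selection threshold:
#' features ranked at or above the knee form the auxiliary search task, so
#' `selected_count == knee_index` (the knee feature itself is included).
#'
#' Ties in the maximum distance are resolved toward the smallest index (the
#' more selective cut). An exactly collinear curve has no knee; the fallback
#' selects the top `ceiling(d / 2)` points.
#'
#' @param scores Numeric vector sorted in non-increasing order, length >= 2.
#' @return A list of class `knee_result`: `knee_index` (1-based rank),
#'   `threshold_score`, `selected_count`, `collinear` (logical).
#' @examples
#' detect_knee(c(1.0, 0.9, 0.2, 0.15, 0.1))
#' @export
detect_knee <- function(scores) {
  d <- length(scores)
  if (d < 2L) stop("need at least 2 scores", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (any(diff(scores) > 0)) stop("scores must be sorted in non-increasing order",
                                  call. = FALSE)
  xi <- seq_len(d) - 1           # curve on (0..d-1, s)
  dy <- scores[d] - scores[1L]
  dx <- d - 1
  num <- abs(dy * xi - dx * (scores - scores[1L]))
  dist <- num / sqrt(dy * dy + dx * dx)
  scale <- max(abs(scores[1L]), abs(scores[d]), 1)
  if (max(dist) <= 1e-12 * scale) {
    k <- ceiling(d / 2)
    res <- list(knee_index = k, threshold_score = scores[k],
                selected_count = k, collinear = TRUE)
  } else {
    k <- which.max(dist)          # first maximum: smallest index wins ties
    res <- list(knee_index = k, threshold_score = scores[k],
                selected_count = k, collinear = FALSE)
  }
  class(res) <- "knee_result"
  res
}

#' @export
print.knee_result <- function(x, ...) {
  cat("Knee at rank ", x$knee_index, " (score ", signif(x$threshold_score, 4),
      "), selecting ", x$selected_count, " features",
      if (x$collinear) " [collinear fallback]", "\n", sep = "")
  invisible(x)
}
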