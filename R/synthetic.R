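# Synthetic wide (d >> n) classification data with planted signal, emulating
# the microarray regime: a few class-informative features, noisy redundant
# copies of them, and a sea of pure-noise features.

#' Generate a labeled d >> n dataset with planted informative features
#'
#' Class labels are as balanced as `n_samples` allows. An informative feature
#' j takes values `Normal(c * class_sep * u_j, 1)` in class `c = 0..C-1`,
#' where the sign `u_j` is fixed per feature; each redundant feature is a
#' randomly chosen informative feature plus `Normal(0, redundant_noise_sd)`
#' noise; all remaining features are label-independent `Normal(0, 1)` noise.
#' Feature positions and sample order are shuffled. The output is fully
#' determined by `seed`.
#'
#' @param n_samples,n_features Dataset dimensions.
#' @param n_informative,n_redundant Planted signal and redundant-copy counts
#'   (`n_informative + n_redundant <= n_features`).
#' @param n_classes Number of classes, >= 2 (needs `n_samples >= 2 * n_classes`).
#' @param class_sep Distance between adjacent class means on informative
#'   features, in noise-SD units.
#' @param redundant_noise_sd SD of the noise added to redundant copies.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return An object of class `synthetic_dataset`: list with `data` (tibble
#'   of features `f0001..` plus a `class` factor) and `truth` (list with
#'   integer `informative` and `redundant` feature indices).
#' @examples
#' ds <- make_synthetic_dataset(n_samples = 30, n_features = 50,
#'                              n_informative = 3, n_redundant = 2,
#'                              n_classes = 2, seed = 7)
#' ds$truth$informative
#' @export
make_synthetic_dataset <- function(n_samples = 120, n_features = 500,
                                   n_informative = 10, n_redundant = 20,
                                   n_classes = 3, class_sep = 2,
                                   redundant_noise_sd = 0.3, seed = NULL) {
  if (n_informative + n_redundant > n_features) {
    stop("n_informative + n_redundant must be <= n_features", call. = FALSE)
  }
  if (n_classes < 2L) stop("need >= 2 classes", call. = FALSE)
  if (n_samples < 2L * n_classes) {
    stop("need n_samples >= 2 * n_classes", call. = FALSE)
  }
  if (class_sep <= 0) stop("class_sep must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  n_signal <- n_informative + n_redundant
  signs <- sample(c(-1, 1), n_informative, replace = TRUE)
  positions <- sample.int(n_features, n_signal)
  labels <- rep_len(seq_len(n_classes) - 1L, n_samples)
  labels <- labels[sample.int(n_samples)]

  x <- matrix(NA_real_, n_samples, n_features)
  inf_vals <- matrix(stats::rnorm(n_samples * n_informative), n_samples)
  inf_vals <- inf_vals +
    outer(labels, rep(class_sep, n_informative)) *
    matrix(signs, n_samples, n_informative, byrow = TRUE)
  inf_pos <- positions[seq_len(n_informative)]
  x[, inf_pos] <- inf_vals

  if (n_redundant > 0L) {
    src <- sample.int(n_informative, n_redundant, replace = TRUE)
    red <- inf_vals[, src, drop = FALSE] +
      matrix(stats::rnorm(n_samples * n_redundant, sd = redundant_noise_sd),
             n_samples)
    x[, positions[n_informative + seq_len(n_redundant)]] <- red
  }

  noise_pos <- setdiff(seq_len(n_features), positions)
  x[, noise_pos] <- stats::rnorm(n_samples * length(noise_pos))

  features <- sprintf("f%04d", seq_len(n_features))
  colnames(x) <- features
  data <- tibble::as_tibble(as.data.frame(x))
  data$class <- factor(labels)

  res <- list(
    data = data,
    truth = list(informative = sort(inf_pos),
                 redundant = sort(positions[n_informative +
                                            seq_len(n_redundant)])),
    spec = list(n_samples = n_samples, n_features = n_features,
                n_informative = n_informative, n_redundant = n_redundant,
                n_classes = n_classes, class_sep = class_sep,
                redundant_noise_sd = redundant_noise_sd, seed = seed)
  )
  class(res) <- "synthetic_dataset"
  res
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  s <- x$spec
  cat("Synthetic labeled dataset: ", s$n_samples, " samples x ", s$n_features,
      " features, ", s$n_classes, " classes\n", sep = "")
  cat("  planted: ", s$n_informative, " informative + ", s$n_redundant,
      " redundant (class_sep = ", s$class_sep, ")\n", sep = "")
  invisible(x)
}

#' Recall of the planted informative features
#'
#' Fraction of the truly informative features present in a selection;
#' ignores precision by design.
#'
#' @param selected Logical mask over features, integer feature indices, or
#'   feature names of the form produced by [make_synthetic_dataset()].
#' @param truth The `truth` element of a `synthetic_dataset` (or a
#'   `synthetic_dataset` itself).
#' @return Recall in \[0,1\].
#' @export
informative_recall <- function(selected, truth) {
  if (inherits(truth, "synthetic_dataset")) truth <- truth$truth
  if (is.logical(selected)) {
    idx <- which(selected)
  } else if (is.character(selected)) {
    idx <- as.integer(sub("^f", "", selected))
  } else {
    idx <- as.integer(selected)
  }
  length(intersect(idx, truth$informative)) / length(truth$informative)
}
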