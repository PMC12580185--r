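# Delimited-table readers/writers for labeled sample-by-feature data.

#' Read a labeled sample-by-feature table
#'
#' Expects delimited text with one row per sample, numeric feature columns
#' and one label column. The label becomes a factor; every other column must
#' parse as a finite number (a missing or non-numeric cell is an error naming
#' its row and column).
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `delim` is given.
#' @param label Name of the label column (default `"class"`).
#' @param delim Optional explicit field delimiter.
#' @return A tibble with numeric feature columns and a factor label column,
#'   with the label code map in the `label_levels` attribute.
#' @export
read_labeled_table <- function(path, label = "class", delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (!label %in% names(raw)) {
    stop("label column '", label, "' not found in ", path, call. = FALSE)
  }
  feats <- setdiff(names(raw), label)
  for (f in feats) {
    v <- raw[[f]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0L) {
        stop("non-numeric value at row ", bad[1L], ", column '", f, "'",
             call. = FALSE)
      }
      v <- num
      raw[[f]] <- v
    }
    if (anyNA(v)) {
      stop("missing value at row ", which(is.na(v))[1L], ", column '", f, "'",
           call. = FALSE)
    }
  }
  raw[[label]] <- factor(raw[[label]])
  attr(raw, "label_levels") <- levels(raw[[label]])
  raw
}

#' Write a labeled table (and optionally a truth sidecar)
#'
#' @param data Data frame to write.
#' @param path Output path; delimiter inferred as in [read_labeled_table()].
#' @param truth Optional `truth` list from [make_synthetic_dataset()]; when
#'   given, the planted feature indices are written next to `path` with a
#'   `_truth.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(data, path, truth = NULL) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  if (!is.null(truth)) {
    if (inherits(truth, "synthetic_dataset")) truth <- truth$truth
    side <- tibble::tibble(
      feature_index = c(truth$informative, truth$redundant),
      role = rep(c("informative", "redundant"),
                 c(length(truth$informative), length(truth$redundant))))
    readr::write_csv(side, sub("\\.[^.]+$", "_truth.csv", path))
  }
  invisible(path)
}
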