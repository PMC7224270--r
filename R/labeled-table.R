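#' Labeled feature tables
#'
#' A `labeled_table` is the universal sample container of the package: a
#' numeric feature matrix (one row per sample) plus integer class codes
#' `0..K-1`. Codes are always assigned by lexicographic sort of the original
#' label strings, so the encoding is reproducible across files and runs, and
#' the original strings are kept in `label_names`.
#'
#' @param features numeric matrix, `n` samples by `d` features; all values
#'   must be finite.
#' @param labels integer class codes in `0..K-1`, length `n`.
#' @param label_names character vector of length `K`: the original label
#'   strings, in code order.
#' @param feature_names character vector of length `d`.
#' @return An object of class `labeled_table`.
#' @export
labeled_table <- function(features, labels, label_names, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  feature_names <- feature_names %||% colnames(features) %||%
    paste0("x", seq_len(ncol(features)))
  colnames(features) <- feature_names
  x <- structure(
    list(features = features, labels = labels,
         label_names = as.character(label_names),
         feature_names = as.character(feature_names)),
    class = "labeled_table")
  validate_labeled_table(x)
}

validate_labeled_table <- function(x) {
  n <- nrow(x$features)
  if (n < 1L) abort("a labeled_table needs at least one sample")
  if (length(x$labels) != n)
    abort("labels length must equal the number of feature rows")
  if (!all(is.finite(x$features)))
    abort("all feature values must be finite")
  K <- length(x$label_names)
  if (any(x$labels < 0L | x$labels >= K))
    abort(sprintf("label codes must lie in 0..%d", K - 1L))
  if (length(x$feature_names) != ncol(x$features))
    abort("feature_names length must equal the number of feature columns")
  x
}

#' Build a labeled table from a data frame
#'
#' All non-label columns must be numeric; the label column may be character,
#' factor or numeric and is re-encoded to contiguous codes `0..K-1` in sorted
#' order of the original label strings.
#'
#' @param data a data frame (or tibble).
#' @param label_col name of the label column.
#' @param label_names optional fixed encoding (character vector); labels not
#'   present in it are an error. Used to force a shared encoding across
#'   domains.
#' @return A `labeled_table`.
#' @export
as_labeled_table <- function(data, label_col, label_names = NULL) {
  data <- as.data.frame(data)
  if (!label_col %in% names(data))
    abort(sprintf("label column '%s' not found", label_col), class = "metl_schema_error")
  raw_labels <- as.character(data[[label_col]])
  feat <- data[setdiff(names(data), label_col)]
  bad <- names(feat)[!vapply(feat, is.numeric, logical(1))]
  if (length(bad))
    abort(sprintf("non-numeric feature column(s): %s", paste(bad, collapse = ", ")),
          class = "metl_parse_error")
  if (is.null(label_names)) {
    label_names <- sort(unique(raw_labels))
  } else if (!all(raw_labels %in% label_names)) {
    abort("labels outside the supplied encoding", class = "metl_schema_error")
  }
  if (length(label_names) < 2L)
    abort("need at least 2 classes", class = "metl_validation_error")
  labeled_table(as.matrix(feat), match(raw_labels, label_names) - 1L,
                label_names, names(feat))
}

#' Read a labeled table from delimited text
#'
#' @param path file path to a delimited text file with a header row.
#' @param label_col name of the label column.
#' @param delimiter field delimiter, `","` (default) or `"\t"`.
#' @inheritParams as_labeled_table
#' @return A `labeled_table`.
#' @export
read_labeled_table <- function(path, label_col, delimiter = ",",
                               label_names = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  data <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
                            progress = FALSE)
  if (!label_col %in% names(data))
    abort(sprintf("label column '%s' not found in %s", label_col, path),
          class = "metl_schema_error")
  feat_cols <- setdiff(names(data), label_col)
  for (cl in feat_cols) {
    if (!is.numeric(data[[cl]])) {
      parsed <- suppressWarnings(as.numeric(data[[cl]]))
      if (anyNA(parsed))
        abort(sprintf("non-numeric value in feature column '%s' at row %d",
                      cl, which(is.na(parsed))[1L]),
              class = "metl_parse_error")
      data[[cl]] <- parsed
    }
  }
  as_labeled_table(data, label_col, label_names = label_names)
}

#' Write a labeled table as delimited text
#'
#' Inverse of [read_labeled_table()]: original label strings are restored in
#' the label column.
#'
#' @param table a `labeled_table`.
#' @param path output file path.
#' @param label_col name for the label column.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_labeled_table <- function(table, path, label_col = "label",
                                delimiter = ",") {
  df <- as_tibble(table, label_col = label_col)
  readr::write_delim(df, path, delim = delimiter)
  invisible(path)
}

#' @importFrom tibble as_tibble
#' @exportS3Method tibble::as_tibble
as_tibble.labeled_table <- function(x, ..., label_col = "label") {
  out <- tibble::as_tibble(as.data.frame(x$features))
  out[[label_col]] <- x$label_names[x$labels + 1L]
  out
}

#' @export
print.labeled_table <- function(x, ...) {
  cat(sprintf("<labeled_table> %d samples x %d features, %d classes (%s)\n",
              nrow(x$features), ncol(x$features), length(x$label_names),
              paste(x$label_names, collapse = ", ")))
  counts <- tabulate(x$labels + 1L, length(x$label_names))
  cat("  class counts:", paste(counts, collapse = "/"), "\n")
  invisible(x)
}

n_samples <- function(x) nrow(x$features)

subset_table <- function(x, idx) {
  labeled_table(x$features[idx, , drop = FALSE], x$labels[idx],
                x$label_names, x$feature_names)
}

bind_tables <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  ref <- parts[[1L]]
  for (p in parts[-1L]) check_compatible(ref, p)
  labeled_table(do.call(rbind, lapply(parts, `[[`, "features")),
                unlist(lapply(parts, `[[`, "labels")),
                ref$label_names, ref$feature_names)
}

check_compatible <- function(a, b) {
  if (!identical(a$label_names, b$label_names) ||
      !identical(a$feature_names, b$feature_names))
    abort("domains must share feature names and label encoding",
          class = "metl_validation_error")
  invisible(TRUE)
}

#' Domain wrapper
#'
#' Tags a `labeled_table` with its role in a transfer problem.
#'
#' @param table a `labeled_table`.
#' @param role `"source"` or `"target"`.
#' @param index integer domain id.
#' @return An object of class `domain_set`.
#' @export
domain_set <- function(table, role = c("source", "target"), index = 1L) {
  role <- match.arg(role)
  structure(list(role = role, index = as.integer(index), data = table),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat(sprintf("<domain_set> role=%s index=%d\n", x$role, x$index))
  print(x$data)
  invisible(x)
}

as_table <- function(x, label_col = "label") {
  if (inherits(x, "labeled_table")) return(x)
  if (inherits(x, "domain_set")) return(x$data)
  if (is.data.frame(x)) return(as_labeled_table(x, label_col))
  abort("expected a data frame, labeled_table or domain_set")
}

#' Stratified target train/test split
#'
#' Mirrors the evaluation protocol for label-scarce targets: a fixed fraction
#' of the target is held out as the test set, and only `label_ratio` of the
#' remainder is kept as the labeled training pool (e.g. `test_fraction = 0.7`
#' and `label_ratio = 0.1` keeps 70% for testing and labels 10% of the
#' remaining 30%). Both parts are stratified by class; the training pool is
#' floored at one sample per class.
#'
#' @param table a `labeled_table` (or data frame with `label_col`).
#' @param test_fraction proportion in (0,1) of samples held out for testing.
#' @param label_ratio proportion in (0,1] of the non-test samples used as
#'   labeled training data.
#' @param seed integer seed; equal seeds give identical splits.
#' @param label_col label column when `table` is a data frame.
#' @return A list with `labeled_table` elements `train` and `test`.
#' @export
split_target <- function(table, test_fraction = 0.7, label_ratio = 0.1,
                         seed = 1L, label_col = "label") {
  table <- as_table(table, label_col)
  stopifnot(test_fraction > 0, test_fraction < 1,
            label_ratio > 0, label_ratio <= 1)
  n <- n_samples(table)
  K <- length(table$label_names)
  n_test <- round(test_fraction * n)
  n_train <- max(K, round(label_ratio * (n - n_test)))
  with_seed(seed, {
    by_class <- split(seq_len(n), table$labels)
    # stratified test allocation, largest-remainder rounding to hit n_test
    exact <- vapply(by_class, length, integer(1)) * test_fraction
    take <- floor(exact)
    short <- n_test - sum(take)
    if (short > 0) {
      ord <- order(exact - take, decreasing = TRUE)
      take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1L
    } else if (short < 0) {
      ord <- order(exact - take)
      k <- 0L
      for (j in ord) {
        if (k == -short) break
        if (take[j] > 0) { take[j] <- take[j] - 1L; k <- k + 1L }
      }
    }
    # never swallow a whole class into the test set
    for (j in seq_along(take))
      if (take[j] >= length(by_class[[j]])) take[j] <- length(by_class[[j]]) - 1L
    test_idx <- unlist(lapply(seq_along(by_class), function(j)
      sample_from(by_class[[j]], take[j])), use.names = FALSE)
    rest <- split(setdiff(seq_len(n), test_idx),
                  table$labels[setdiff(seq_len(n), test_idx)])
    exact_tr <- vapply(rest, length, integer(1)) / sum(lengths(rest)) * n_train
    take_tr <- floor(exact_tr)
    ord <- order(exact_tr - take_tr, decreasing = TRUE)
    short <- n_train - sum(take_tr)
    if (short > 0)
      take_tr[ord[seq_len(short)]] <- take_tr[ord[seq_len(short)]] + 1L
    if (any(take_tr == 0)) {            # floor: one labeled sample per class
      warn("some classes floored to one training sample")
      while (any(take_tr == 0)) {
        give <- which.max(take_tr)
        if (take_tr[give] > 1L && sum(take_tr) >= n_train)
          take_tr[give] <- take_tr[give] - 1L
        take_tr[which(take_tr == 0)[1L]] <- 1L
      }
    }
    take_tr <- pmin(take_tr, lengths(rest))
    train_idx <- unlist(lapply(seq_along(rest), function(j)
      sample_from(rest[[j]], take_tr[j])), use.names = FALSE)
  })
  list(train = subset_table(table, sort(train_idx)),
       test = subset_table(table, sort(test_idx)))
}
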