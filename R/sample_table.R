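#' Patient case-report table
#'
#' Container for an `n x m` clinical feature matrix with sample identifiers,
#' feature (attribute) names and an optional binary outcome label
#' (1 = early cancer found, 0 = not). All downstream stages of the
#' prediction pipeline consume this type.
#'
#' @param X numeric matrix, `n` samples by `m` features; all entries finite.
#' @param sample_ids character vector of length `n`; unique, opaque IDs.
#'   Defaults to `"S1" ... "Sn"`.
#' @param feature_names character vector of length `m`. Defaults to
#'   `"f1" ... "fm"`.
#' @param y optional integer/numeric vector of length `n` with entries in
#'   `{0, 1}`; omit for unlabeled prediction input.
#'
#' @return An object of class `sample_table`: a list with elements
#'   `sample_ids`, `feature_names`, `X` and `y` (possibly `NULL`).
#' @export
#' @examples
#' tab <- sample_table(matrix(1:6, 3, 2), y = c(0, 1, 0))
#' tab$X
sample_table <- function(X, sample_ids = NULL, feature_names = NULL, y = NULL) {
  if (!is.matrix(X) || !is.numeric(X)) {
    config_error("`X` must be a numeric matrix")
  }
  storage.mode(X) <- "double"
  n <- nrow(X); m <- ncol(X)
  if (n < 1L || m < 1L) config_error("need n >= 1 samples and m >= 1 features, got %d x %d", n, m)
  if (!all(is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    config_error("non-finite feature value at row %d, column %d (missing values are rejected, not imputed)",
                 bad[1L], bad[2L])
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) config_error("length(sample_ids) != nrow(X)")
  if (anyDuplicated(sample_ids)) {
    config_error("duplicate sample IDs: %s",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(m))
  feature_names <- as.character(feature_names)
  if (length(feature_names) != m) config_error("length(feature_names) != ncol(X)")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != n) config_error("length(y) != nrow(X)")
    if (!is_binary01(y)) {
      bad <- which(!(y %in% c(0, 1)) | !is.finite(y))[1L]
      config_error("label of sample '%s' (row %d) is not 0/1", sample_ids[bad], bad)
    }
  }
  dimnames(X) <- list(sample_ids, feature_names)
  structure(list(sample_ids = sample_ids, feature_names = feature_names,
                 X = X, y = y),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d features%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$y)) ", unlabeled"
              else sprintf(", %d positives (%.1f%%)", sum(x$y), 100 * mean(x$y))))
  invisible(x)
}

#' @export
dim.sample_table <- function(x) dim(x$X)

#' Read a patient case-report CSV
#'
#' Expected dialect: UTF-8, comma-separated, one header row, first column
#' holds the sample ID, remaining columns are numeric features; an optional
#' label column (by default named `"label"`) holds the binary outcome and is
#' stripped from the feature block. Column order is preserved. Missing or
#' non-numeric feature cells are an error — the pipeline assumes a complete
#' matrix.
#'
#' @param path path to an existing CSV file.
#' @param label_column name of the label column, or `NULL` for unlabeled
#'   input. When omitted, a column named `"label"` is used if present.
#' @return a [sample_table].
#' @seealso [write_sample_csv()]
#' @export
read_sample_csv <- function(path, label_column = "label") {
  if (!file.exists(path)) config_error("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) config_error("CSV must have an ID column plus at least one feature column")
  explicit <- !is.null(label_column) && !missing(label_column)
  ids <- raw[[1L]]
  feat <- raw[, -1L, drop = FALSE]
  y <- NULL
  if (!is.null(label_column) && label_column %in% names(feat)) {
    lab_raw <- feat[[label_column]]
    feat <- feat[, setdiff(names(feat), label_column), drop = FALSE]
    lab <- suppressWarnings(as.numeric(lab_raw))
    bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
    if (length(bad)) {
      config_error("label '%s' of sample '%s' (row %d) is not 0/1",
                   lab_raw[bad[1L]], ids[bad[1L]], bad[1L])
    }
    y <- lab
  } else if (explicit && !is.null(label_column)) {
    config_error("label column '%s' not present in %s", label_column, path)
  }
  if (ncol(feat) < 1L) config_error("no feature columns left after removing the label")
  X <- matrix(NA_real_, nrow(feat), ncol(feat))
  for (j in seq_len(ncol(feat))) {
    v <- suppressWarnings(as.numeric(feat[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      config_error("non-numeric feature cell '%s' at row %d, column '%s'",
                   feat[[j]][bad[1L]], bad[1L], names(feat)[j])
    }
    X[, j] <- v
  }
  sample_table(X, sample_ids = ids, feature_names = names(feat), y = y)
}

#' Write a patient case-report CSV
#'
#' Values are written with 17 significant digits so that
#' `read_sample_csv(write_sample_csv(t))` round-trips doubles exactly.
#'
#' @param table a [sample_table].
#' @param path output path; parent directory must exist and be writable.
#' @return `path`, invisibly.
#' @export
write_sample_csv <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  dir <- dirname(path)
  if (!dir.exists(dir)) config_error("directory does not exist: %s", dir)
  header <- c("sample_id", table$feature_names, if (!is.null(table$y)) "label")
  fmt_num <- function(v) sprintf("%.17g", v)
  rows <- vapply(seq_along(table$sample_ids), function(i) {
    paste(c(table$sample_ids[i], fmt_num(table$X[i, ]),
            if (!is.null(table$y)) fmt_num(table$y[i])),
          collapse = ",")
  }, character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(header, collapse = ","), rows), con, useBytes = TRUE)
  invisible(path)
}

#' Indices of a train/test partition
#'
#' @param train_idx,test_idx integer vectors of 1-based row indices; they
#'   must be disjoint and their union must be exactly `1..n`.
#' @param n total number of samples.
#' @return an object of class `split_indices`.
#' @export
split_indices <- function(train_idx, test_idx, n) {
  train_idx <- sort(as.integer(train_idx))
  test_idx <- sort(as.integer(test_idx))
  if (length(intersect(train_idx, test_idx))) config_error("train and test indices overlap")
  if (!identical(sort(c(train_idx, test_idx)), seq_len(n))) {
    config_error("train and test indices must partition 1..%d exactly", n)
  }
  structure(list(train_idx = train_idx, test_idx = test_idx, n = as.integer(n)),
            class = "split_indices")
}
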