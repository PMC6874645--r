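#' Z-score standardization per feature column
#'
#' Standardizes each feature column to mean 0 and standard deviation 1,
#' using the population (divide-by-n) standard deviation so the
#' unit-variance postcondition is exact. Constant columns carry no
#' information for any downstream stage; they are mapped to all-zeros
#' rather than raising an error, and are flagged in the returned stats.
#'
#' @param x a [sample_table] or a numeric matrix.
#' @param standardize_binary if `FALSE`, columns whose values are all in
#'   `{0, 1}` (e.g. gender, smoking history) are passed through unchanged
#'   instead of being standardized. Default `TRUE`: binary indicators are
#'   treated like any other column.
#' @return a list with `Z` (the standardized matrix) and `stats`, an object
#'   of class `column_stats` holding `mu`, `sigma`, `constant` (logical),
#'   `passthrough` (logical) and, once [rescale_nonnegative()] has been
#'   applied, `shift_min` and `shift_range`.
#' @export
#' @examples
#' zscore_fit_transform(matrix(c(1, 2, 3), ncol = 1))$Z
zscore_fit_transform <- function(x, standardize_binary = TRUE) {
  X <- if (inherits(x, "sample_table")) x$X else x
  if (!is.matrix(X) || !is.numeric(X)) config_error("input must be a numeric matrix or sample_table")
  n <- nrow(X); m <- ncol(X)
  mu <- colMeans(X)
  sigma <- sqrt(colMeans(sweep(X, 2L, mu, "-")^2))
  constant <- sigma < 1e-12
  passthrough <- if (standardize_binary) rep(FALSE, m) else apply(X, 2L, is_binary01)
  Z <- sweep(X, 2L, mu, "-")
  Z <- sweep(Z, 2L, ifelse(constant, 1, sigma), "/")
  Z[, constant] <- 0
  if (any(passthrough)) Z[, passthrough] <- X[, passthrough]
  stats <- structure(
    list(mu = mu, sigma = sigma, constant = constant, passthrough = passthrough,
         shift_min = NULL, shift_range = NULL),
    class = "column_stats")
  list(Z = Z, stats = stats)
}

#' Restore nonnegativity after standardization
#'
#' Z-scores are signed, but both the factorization stage (which requires
#' `W >= 0, H >= 0`) and the belief-network stage (whose visible units are
#' probabilities) need inputs in `[0, 1]`. This maps each column affinely
#' onto `[0, 1]` (min to 0, max to 1), preserving the within-column order;
#' zero-range columns map to all zeros. The fitted per-column minima and
#' ranges are stored in `stats` so new samples can be transformed
#' identically (see [preprocess_apply()]).
#'
#' @param Z standardized matrix from [zscore_fit_transform()].
#' @param stats the matching `column_stats`.
#' @return a list with `Xp` (matrix in `[0, 1]`) and the updated `stats`.
#' @export
rescale_nonnegative <- function(Z, stats) {
  stopifnot(inherits(stats, "column_stats"))
  if (!all(is.finite(Z))) config_error("standardized matrix contains non-finite values")
  mins <- apply(Z, 2L, min)
  maxs <- apply(Z, 2L, max)
  ranges <- maxs - mins
  stats$shift_min <- mins
  stats$shift_range <- ranges
  list(Xp = minmax_apply(Z, mins, ranges), stats = stats)
}

#' Fit the full preprocessing transform
#'
#' Convenience wrapper: Z-score standardization followed by per-column
#' min-max rescaling to `[0, 1]`.
#'
#' @inheritParams zscore_fit_transform
#' @return list with `Xp` (nonnegative matrix in `[0, 1]`) and fitted
#'   `stats`.
#' @export
preprocess_fit <- function(x, standardize_binary = TRUE) {
  z <- zscore_fit_transform(x, standardize_binary = standardize_binary)
  rescale_nonnegative(z$Z, z$stats)
}

#' Apply a fitted preprocessing transform to new samples
#'
#' Uses the stored column means, standard deviations, minima and ranges;
#' values falling outside the fitted range are clipped into `[0, 1]`.
#'
#' @param X numeric matrix with the same columns as the fitting data.
#' @param stats fitted `column_stats` (with rescale parameters).
#' @return matrix in `[0, 1]`.
#' @export
preprocess_apply <- function(X, stats) {
  stopifnot(inherits(stats, "column_stats"))
  if (is.null(stats$shift_min)) config_error("stats lack rescale parameters; run rescale_nonnegative() first")
  if (ncol(X) != length(stats$mu)) config_error("column count mismatch: %d vs %d fitted", ncol(X), length(stats$mu))
  Z <- sweep(X, 2L, stats$mu, "-")
  Z <- sweep(Z, 2L, ifelse(stats$constant, 1, stats$sigma), "/")
  Z[, stats$constant] <- 0
  if (any(stats$passthrough)) Z[, stats$passthrough] <- X[, stats$passthrough]
  minmax_apply(Z, stats$shift_min, stats$shift_range, clip = TRUE)
}

#' Save / load fitted column statistics
#'
#' JSON sidecar so the identical transform can be applied to new samples in
#' a later session.
#'
#' @param stats a `column_stats` object.
#' @param path file path.
#' @return `write_column_stats` returns `path` invisibly;
#'   `read_column_stats` returns a `column_stats`.
#' @export
write_column_stats <- function(stats, path) {
  stopifnot(inherits(stats, "column_stats"))
  jsonlite::write_json(unclass(stats), path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_column_stats
#' @export
read_column_stats <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mu = as.numeric(raw$mu), sigma = as.numeric(raw$sigma),
                 constant = as.logical(raw$constant),
                 passthrough = as.logical(raw$passthrough),
                 shift_min = if (length(raw$shift_min)) as.numeric(raw$shift_min),
                 shift_range = if (length(raw$shift_range)) as.numeric(raw$shift_range)),
            class = "column_stats")
}
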