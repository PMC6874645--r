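#' Fit a linear support vector machine in the dual
#'
#' Solves the soft-margin dual
#' `min_a 1/2 sum_ij a_i a_j y_i y_j (x_i . x_j) - sum_i a_i` subject to
#' `sum_i a_i y_i = 0` and `0 <= a_i <= C`, by sequential minimal
#' optimization: the maximal-violating pair (ties broken by lowest index)
#' is updated analytically until the KKT gap falls below `tol`. Labels in
#' `{0, 1}` are recoded internally to `-1, +1`. `C = Inf` gives the hard
#' margin. The solver is deterministic; `seed` is accepted for interface
#' symmetry only.
#'
#' @param X numeric feature matrix, one training sample per row.
#' @param y labels in `{0, 1}`; both classes must be present.
#' @param C soft-margin penalty (default 1; `Inf` = hard margin).
#' @param tol KKT-violation stopping tolerance (default `1e-3`). The
#'   intercept is the mean of `y_i - w . x_i` over free support vectors.
#' @param max_iter cap on pair updates (default `200 * n`).
#' @param seed unused (deterministic solver).
#' @return object of class `svm_model`: `w`, `b`, `alpha`, `support_idx`
#'   (indices with `a_i` above threshold), `C`, `dual_objective`,
#'   `converged`.
#' @export
#' @examples
#' fit <- svm_fit(rbind(c(1, 1), c(-1, -1)), c(1, 0), C = Inf)
#' fit$w  # (0.5, 0.5); b = 0; margin 2*sqrt(2)
svm_fit <- function(X, y, C = 1, tol = 1e-3, max_iter = NULL, seed = 1L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  y <- as.numeric(y)
  if (!is_binary01(y)) stopf("labels must be 0/1")
  n <- nrow(X)
  if (n < 2L) stopf("need at least 2 training samples")
  if (length(unique(y)) < 2L) stopf("training set contains a single class")
  if (length(y) != n) stopf("length(y) != nrow(X)")
  ys <- ifelse(y == 1, 1, -1)
  K <- tcrossprod(X)
  if (is.null(max_iter)) max_iter <- 200L * n

  alpha <- numeric(n)
  grad <- rep(-1, n)             # gradient of the dual objective at alpha = 0
  eps_a <- 1e-8
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # F_i = -y_i * grad_i; violating pair: max over I_up vs min over I_low
    Fv <- -ys * grad
    up <- (ys == 1 & alpha < C - eps_a) | (ys == -1 & alpha > eps_a)
    lo <- (ys == -1 & alpha < C - eps_a) | (ys == 1 & alpha > eps_a)
    if (!any(up) || !any(lo)) { converged <- TRUE; break }
    Fu <- ifelse(up, Fv, -Inf)
    Fl <- ifelse(lo, Fv, Inf)
    i <- which.max(Fu)
    j <- which.min(Fl)
    if (Fv[i] - Fv[j] < tol) { converged <- TRUE; break }

    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    # E_i = u_i - y_i = -F_i
    Ei <- -Fv[i]; Ej <- -Fv[j]
    aj_old <- alpha[j]; ai_old <- alpha[i]
    aj_new <- aj_old + ys[j] * (Ei - Ej) / eta
    if (ys[i] != ys[j]) {
      L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
    }
    aj_new <- min(max(aj_new, L), H)
    ai_new <- ai_old + ys[i] * ys[j] * (aj_old - aj_new)
    dalpha_i <- ai_new - ai_old; dalpha_j <- aj_new - aj_old
    if (abs(dalpha_j) < 1e-14) { converged <- TRUE; break }
    alpha[i] <- ai_new; alpha[j] <- aj_new
    grad <- grad + dalpha_i * ys[i] * ys * K[, i] + dalpha_j * ys[j] * ys * K[, j]
  }
  if (!converged) warning("SMO did not reach the KKT tolerance within max_iter")

  w <- as.vector(crossprod(X, alpha * ys))
  free <- alpha > eps_a & alpha < C - eps_a
  sv <- alpha > eps_a
  b <- if (any(free)) {
    mean(ys[free] - X[free, , drop = FALSE] %*% w)
  } else if (any(sv)) {
    mean(ys[sv] - X[sv, , drop = FALSE] %*% w)
  } else 0
  dual_obj <- 0.5 * sum((alpha * ys) * (K %*% (alpha * ys))) - sum(alpha)
  structure(list(w = w, b = as.numeric(b), alpha = alpha,
                 support_idx = which(sv), C = C,
                 dual_objective = dual_obj, converged = converged),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model> %d features, %d support vectors, C = %s, margin %.4g\n",
              length(x$w), length(x$support_idx), format(x$C), svm_margin(x)))
  invisible(x)
}

#' Predict class labels with a fitted linear SVM
#'
#' Decision rule `sign(w . x + b)`: label 1 (the positive/cancer class)
#' when `w . x + b >= 0` — a point exactly on the hyperplane is assigned
#' to the positive class, the clinically conservative tie rule — else 0.
#'
#' @param model fitted `svm_model`.
#' @param X feature matrix (or single feature vector).
#' @return numeric vector of labels in `{0, 1}`.
#' @export
svm_predict <- function(model, X) {
  stopifnot(inherits(model, "svm_model"))
  if (is.null(dim(X))) X <- matrix(X, ncol = length(model$w))
  if (ncol(X) != length(model$w)) {
    stopf("feature count mismatch: %d vs %d", ncol(X), length(model$w))
  }
  as.numeric(as.vector(X %*% model$w) + model$b >= 0)
}

#' Geometric margin of a linear SVM
#'
#' The width `2 / ||w||` of the band between the two support hyperplanes.
#'
#' @param model fitted `svm_model` with a nonzero weight vector.
#' @return positive real.
#' @export
svm_margin <- function(model) {
  stopifnot(inherits(model, "svm_model"))
  nw <- sqrt(sum(model$w^2))
  if (nw <= 0) stopf("zero weight vector has no margin")
  2 / nw
}

#' Save / load a fitted SVM
#'
#' @param model `svm_model`.
#' @param path file path.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "svm_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$C <- if (is.character(raw$C)) Inf else raw$C   # Inf survives as a string
  structure(list(w = as.numeric(raw$w), b = raw$b, alpha = as.numeric(raw$alpha),
                 support_idx = as.integer(raw$support_idx), C = raw$C,
                 dual_objective = raw$dual_objective,
                 converged = as.logical(raw$converged)),
            class = "svm_model")
}
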