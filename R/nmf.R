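#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative `n x m` matrix `Xp` as `W H` with
#' `W >= 0` (`n x k`, the "base matrix" whose rows are the reduced samples)
#' and `H >= 0` (`k x m`, the "weight matrix" of attribute loadings),
#' minimizing the squared Frobenius error
#' `||Xp - W H||_F^2` with the Lee-Seung multiplicative update rules.
#' Denominators are guarded with `eps = 1e-12`; the objective is therefore
#' non-increasing along the iteration trace (up to `1e-9` slack). Several
#' random restarts are run and the factorization with the lowest final
#' objective is returned; results are fully determined by `seed`.
#'
#' @param Xp nonnegative numeric matrix.
#' @param k latent dimension, `1 <= k <= min(n, m)`.
#' @param max_iter maximum multiplicative updates per restart (default 500).
#' @param tol stop when the relative objective decrease falls below this
#'   (default `1e-6`).
#' @param restarts number of seeded initializations (default 5).
#' @param seed integer; restart `r` uses `seed + r - 1`.
#' @param init optional list with matrices `W` and `H` to use as the single
#'   starting point (overrides `restarts`); used mainly for equivariance
#'   testing and warm starts.
#' @param init_method `"hybrid"` (default; the first restart starts from
#'   the SVD-based NNDSVD point with zeros perturbed to small seeded
#'   positives, remaining restarts are random), `"random"`, or
#'   `"nndsvd"` (single NNDSVD restart). NNDSVD greatly accelerates
#'   convergence on near-low-rank matrices, where plain multiplicative
#'   updates stall.
#' @param enforce_compression if `TRUE`, require `(n + m) k < n m`, the
#'   condition under which the factorization compresses storage.
#' @return object of class `nmf_model`: list with `W`, `H`, `k`,
#'   `objective_trace` (per-iteration `||Xp - WH||_F^2`, starting at the
#'   initialization), `seed`, `restart` (index of the winning restart) and
#'   `converged`.
#' @references Lee & Seung (1999) Nature 401:788; Lee & Seung (2000)
#'   NIPS 13 (multiplicative update algorithms).
#' @export
#' @examples
#' X <- outer(1:4, 1:3) + 0
#' m <- nmf_factorize(X, k = 1, seed = 1)
#' norm(X - m$W %*% m$H, "F") / norm(X, "F") # ~0: exact rank-1 case
nmf_factorize <- function(Xp, k, max_iter = 500L, tol = 1e-6, restarts = 5L,
                          seed = 1L, init = NULL, enforce_compression = FALSE,
                          init_method = c("hybrid", "random", "nndsvd")) {
  init_method <- match.arg(init_method)
  if (!is.matrix(Xp) || !is.numeric(Xp)) config_error("`Xp` must be a numeric matrix")
  n <- nrow(Xp); m <- ncol(Xp)
  if (any(Xp < 0)) {
    bad <- which(Xp < 0, arr.ind = TRUE)[1L, ]
    config_error("negative entry at row %d, column %d: nonnegative input required",
                 bad[1L], bad[2L])
  }
  if (k < 1L || k > min(n, m)) config_error("k = %d out of range [1, %d]", k, min(n, m))
  if (enforce_compression && !((n + m) * k < n * m)) {
    config_error("(n + m) * k = %d does not compress n * m = %d", (n + m) * k, n * m)
  }
  eps <- 1e-12
  scale0 <- sqrt(mean(Xp) / k)

  run_once <- function(W, H) {
    trace <- numeric(max_iter + 1L)
    R <- Xp - W %*% H
    trace[1L] <- sum(R * R)
    used <- 1L
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, Xp)) / (crossprod(W, W) %*% H + eps)
      W <- W * (Xp %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
      R <- Xp - W %*% H
      f <- sum(R * R)
      used <- used + 1L
      trace[used] <- f
      prev <- trace[used - 1L]
      if (prev - f < tol * max(prev, eps)) { converged <- TRUE; break }
    }
    list(W = W, H = H, trace = trace[seq_len(used)], converged = converged)
  }

  best <- NULL; best_restart <- NA_integer_
  if (!is.null(init)) {
    stopifnot(is.list(init), !is.null(init$W), !is.null(init$H))
    if (any(init$W < 0) || any(init$H < 0)) config_error("init factors must be nonnegative")
    best <- run_once(init$W, init$H)
    best_restart <- 0L
  } else {
    if (init_method == "nndsvd") restarts <- 1L
    for (r in seq_len(restarts)) {
      fit <- with_seed(derive_seed(seed, r - 1L), {
        if (r == 1L && init_method != "random") {
          st <- nndsvd_init(Xp, k)
          run_once(st$W, st$H)
        } else {
          W0 <- matrix(stats::runif(n * k), n, k) * scale0
          H0 <- matrix(stats::runif(k * m), k, m) * scale0
          run_once(W0, H0)
        }
      })
      if (is.null(best) || utils::tail(fit$trace, 1L) < utils::tail(best$trace, 1L)) {
        best <- fit; best_restart <- r
      }
    }
  }
  structure(list(W = best$W, H = best$H, k = as.integer(k),
                 objective_trace = best$trace, seed = as.integer(seed),
                 restart = best_restart, converged = best$converged),
            class = "nmf_model")
}

# NNDSVD starting point (Boutsidis & Gallopoulos 2008): each leading
# singular-vector pair contributes its dominant sign-consistent part.
# Zeros are perturbed to small positives drawn from the current RNG
# stream (the "ar" variant) so multiplicative updates cannot lock them.
nndsvd_init <- function(Xp, k) {
  n <- nrow(Xp); m <- ncol(Xp)
  sv <- svd(Xp, nu = k, nv = k)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  H[1L, ] <- sqrt(sv$d[1L]) * abs(sv$v[, 1L])
  if (k > 1L) for (j in 2:k) {
    x <- sv$u[, j]; z <- sv$v[, j]
    xp <- pmax(x, 0); xn <- pmax(-x, 0)
    zp <- pmax(z, 0); zn <- pmax(-z, 0)
    nxp <- sqrt(sum(xp^2)); nxn <- sqrt(sum(xn^2))
    nzp <- sqrt(sum(zp^2)); nzn <- sqrt(sum(zn^2))
    if (nxp * nzp >= nxn * nzn) {
      sig <- nxp * nzp
      u <- if (nxp > 0) xp / nxp else xp
      v <- if (nzp > 0) zp / nzp else zp
    } else {
      sig <- nxn * nzn
      u <- if (nxn > 0) xn / nxn else xn
      v <- if (nzn > 0) zn / nzn else zn
    }
    W[, j] <- sqrt(sv$d[j] * sig) * u
    H[j, ] <- sqrt(sv$d[j] * sig) * v
  }
  floor_val <- mean(Xp) / 100
  zw <- W < 1e-11
  W[zw] <- stats::runif(sum(zw)) * floor_val
  zh <- H < 1e-11
  H[zh] <- stats::runif(sum(zh)) * floor_val
  list(W = W, H = H)
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("<nmf_model> %d x %d = (%d x %d)(%d x %d), final objective %.6g (%d iterations)\n",
              nrow(x$W), ncol(x$H), nrow(x$W), x$k, x$k, ncol(x$H),
              utils::tail(x$objective_trace, 1L), length(x$objective_trace) - 1L))
  invisible(x)
}

#' Project new rows onto a fitted weight matrix
#'
#' Solves `min_{w >= 0} ||x - w H||^2` row-wise with `H` held fixed
#' (multiplicative updates on `W` only). This is the strict,
#' no-information-leakage route for mapping held-out samples into the
#' latent space of a factorization fitted on training rows only.
#'
#' @param model fitted `nmf_model` (only `H` is used).
#' @param Xnew nonnegative matrix with `ncol(H)` columns.
#' @param max_iter,tol,seed as in [nmf_factorize()].
#' @return nonnegative matrix `nrow(Xnew) x k`.
#' @export
nmf_project <- function(model, Xnew, max_iter = 500L, tol = 1e-6, seed = 1L) {
  stopifnot(inherits(model, "nmf_model"))
  if (ncol(Xnew) != ncol(model$H)) config_error("column mismatch: %d vs %d", ncol(Xnew), ncol(model$H))
  if (any(Xnew < 0)) config_error("negative entry in projection input")
  H <- model$H
  eps <- 1e-12
  with_seed(seed, {
    W <- matrix(stats::runif(nrow(Xnew) * model$k), nrow(Xnew), model$k) *
      sqrt(mean(Xnew) / model$k)
    HHt <- tcrossprod(H, H)
    XHt <- Xnew %*% t(H)
    f_prev <- Inf
    for (it in seq_len(max_iter)) {
      W <- W * XHt / (W %*% HHt + eps)
      R <- Xnew - W %*% H
      f <- sum(R * R)
      if (f_prev - f < tol * max(f_prev, eps)) break
      f_prev <- f
    }
    W
  })
}

#' Attribute-feature weight report
#'
#' Tabulates the full `k x m` weight matrix `H`: entry `(f, j)` is the
#' nonnegative loading of clinical attribute `j` on extracted feature `f`
#' (interpreted in the source model as the strength of association between
#' the attribute and the latent feature). For each extracted feature the
#' attributes whose weight is at or above the `1 - top_fraction` quantile
#' of that feature's row are flagged as `top`.
#'
#' @param model fitted `nmf_model`.
#' @param feature_names character vector of the `m` attribute names.
#' @param top_fraction fraction of attributes to flag per extracted
#'   feature, in `(0, 1]`; `1` flags all of them.
#' @return `data.frame` with columns `feature_index`, `attribute_name`,
#'   `weight`, `rank` (1 = heaviest within the feature) and `top`, sorted
#'   by feature then descending weight.
#' @export
feature_weight_report <- function(model, feature_names, top_fraction = 0.2) {
  stopifnot(inherits(model, "nmf_model"))
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1) {
    config_error("top_fraction must be in (0, 1]")
  }
  H <- model$H
  m <- ncol(H)
  if (length(feature_names) != m) config_error("need %d attribute names, got %d", m, length(feature_names))
  out <- do.call(rbind, lapply(seq_len(model$k), function(f) {
    w <- H[f, ]
    ord <- order(-w, seq_along(w))  # ties broken by attribute position
    thr <- stats::quantile(w, probs = 1 - top_fraction, names = FALSE, type = 7)
    data.frame(feature_index = f,
               attribute_name = feature_names[ord],
               weight = w[ord],
               rank = seq_len(m),
               top = w[ord] >= thr,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Sweep the latent dimension k
#'
#' Re-runs the downstream pipeline (belief-network feature extraction plus
#' linear SVM under the stratified repeated-split protocol) for each
#' candidate latent dimension and records mean precision, recall and F1 on
#' the held-out splits.
#'
#' Two selections are reported: the raw F1 argmax (`attr(, "argmax_k")`;
#' ties to the smallest k), and the one-standard-error choice
#' (`attr(, "selected_k")`): the smallest k whose mean F1 is within one
#' standard error of the best. Beyond the informative dimension the F1
#' curve typically plateaus with noise, so the argmax drifts across the
#' plateau; the 1-SE rule is the standard parsimony convention for
#' selecting the knee of such a curve (see the methods vignette).
#'
#' @param Xp preprocessed nonnegative matrix (samples x attributes).
#' @param y binary labels, length `nrow(Xp)`.
#' @param k_values integer vector of candidate dimensions within
#'   `[1, min(n, m)]`.
#' @param config an [ecp_config()]; `n_runs` controls how many repeated
#'   splits are averaged per k.
#' @return `data.frame` with one row per k (`k`, `precision`, `recall`,
#'   `f1`, `f1_se`), with the chosen dimension in `attr(, "selected_k")`
#'   and the raw argmax in `attr(, "argmax_k")`.
#' @export
k_sweep <- function(Xp, y, k_values, config = ecp_config()) {
  k_values <- as.integer(k_values)
  if (any(k_values < 1L) || any(k_values > min(dim(Xp)))) {
    config_error("k_values must lie in [1, %d]", min(dim(Xp)))
  }
  rows <- lapply(k_values, function(k) {
    cfg <- config
    cfg$k <- k
    model <- nmf_factorize(Xp, k,
                           max_iter = cfg$nmf_max_iter, tol = cfg$nmf_tol,
                           restarts = cfg$nmf_restarts,
                           seed = derive_seed(cfg$seed, 1000L + k))
    prep <- latent_features(model$W)
    reps <- vapply(seq_len(cfg$n_runs), function(r) {
      res <- run_split(prep, y, cfg, run_seed = derive_seed(cfg$seed, 100000L * k + r))
      c(res$metrics$precision, res$metrics$recall, res$metrics$f1)
    }, numeric(3L))
    c(k = k, precision = mean(reps[1L, ]), recall = mean(reps[2L, ]),
      f1 = mean(reps[3L, ]),
      f1_se = if (cfg$n_runs > 1L) stats::sd(reps[3L, ]) / sqrt(cfg$n_runs) else 0)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  best <- which.max(tab$f1)  # which.max takes the first (smallest k) on ties
  thr <- tab$f1[best] - tab$f1_se[best]
  attr(tab, "argmax_k") <- as.integer(tab$k[best])
  attr(tab, "selected_k") <- as.integer(tab$k[which(tab$f1 >= thr)[1L]])
  tab
}

#' Save / load a factorization
#'
#' Plain-JSON archive of `W`, `H`, `k`, `seed` and the objective trace.
#'
#' @param model `nmf_model`.
#' @param path file path.
#' @export
write_nmf_model <- function(model, path) {
  stopifnot(inherits(model, "nmf_model"))
  jsonlite::write_json(
    list(W = model$W, H = model$H, k = model$k,
         objective_trace = model$objective_trace, seed = model$seed,
         restart = model$restart, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_nmf_model
#' @export
read_nmf_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W = raw$W, H = raw$H, k = as.integer(raw$k),
                 objective_trace = as.numeric(raw$objective_trace),
                 seed = as.integer(raw$seed), restart = as.integer(raw$restart),
                 converged = as.logical(raw$converged)),
            class = "nmf_model")
}
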