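# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; nothing is read from disk.

# Small labeled table for plumbing tests.
tiny_table <- function(n = 12, m = 4, seed = 5) {
  ecpredict:::with_seed(seed, {
    X <- matrix(stats::rexp(n * m), n, m)
    y <- c(rep(1, max(2, round(n / 4))), rep(0, n - max(2, round(n / 4))))
    sample_table(X, y = sample(y))
  })
}

# A faster-but-faithful pipeline configuration for repeated-run tests:
# identical architecture and protocol, training epochs scaled down
# (documented in the methods vignette; the defaults are the full setting).
fast_config <- function(...) {
  args <- utils::modifyList(
    list(pretrain_epochs = 30L, finetune_epochs = 600L,
         nmf_restarts = 2L, nmf_max_iter = 300L),
    list(...))
  do.call(ecp_config, args)
}

# --- Hard-margin linear SVM oracle (2-D), independent of the SMO path ---
# The maximum-margin separator of a linearly separable 2-D set is
# supported by two or three points; enumerate every candidate support set,
# solve each analytically, keep the feasible solution with smallest
# ||w||^2 / 2. Returns list(w, b, objective).
svm_oracle_2d <- function(X, y01) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  best <- NULL
  consider <- function(w, b) {
    if (any(y * (X %*% w + b) < 1 - 1e-9)) return()
    obj <- 0.5 * sum(w^2)
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <<- list(w = as.vector(w), b = b, objective = obj)
    }
  }
  pos <- which(y == 1); neg <- which(y == -1)
  # two support vectors, one per class: w along their difference
  for (i in pos) for (j in neg) {
    d <- X[i, ] - X[j, ]
    nd2 <- sum(d^2)
    if (nd2 < 1e-20) next
    w <- 2 * d / nd2
    b <- 1 - sum(w * X[i, ])
    consider(w, b)
  }
  # three support vectors: two in one class fix the direction
  triple <- function(i1, i2, j, yi) {
    d <- X[i1, ] - X[i2, ]
    if (sum(d^2) < 1e-20) return()
    dir <- c(-d[2], d[1])  # perpendicular in 2-D
    denom <- sum(dir * (X[i1, ] - X[j, ]))
    if (abs(denom) < 1e-12) return()
    w <- 2 * yi * dir / denom  # from w.(x_i1 - x_j) = 2 y_i
    b <- yi - sum(w * X[i1, ])
    consider(w, b)
  }
  if (length(pos) >= 2) for (a in seq_along(pos)) for (b2 in seq_along(pos)) {
    if (a < b2) for (j in neg) triple(pos[a], pos[b2], j, 1)
  }
  if (length(neg) >= 2) for (a in seq_along(neg)) for (b2 in seq_along(neg)) {
    if (a < b2) for (j in pos) triple(neg[a], neg[b2], j, -1)
  }
  best
}

# Random linearly separable 2-D set with a guaranteed margin.
separable_2d <- function(n = 20, seed = 1, gap = 1) {
  ecpredict:::with_seed(seed, {
    y <- rep(c(1, 0), length.out = n)
    X <- matrix(stats::rnorm(n * 2), n, 2)
    X[y == 1, 1] <- abs(X[y == 1, 1]) + gap / 2
    X[y == 0, 1] <- -abs(X[y == 0, 1]) - gap / 2
    list(X = X, y = y)
  })
}

# --- Exact RBM enumeration oracles (small models only) ---
# All 2^d binary vectors as rows.
all_binary <- function(d) {
  as.matrix(expand.grid(rep(list(c(0, 1)), d)))[, d:1, drop = FALSE]
}

# Boltzmann joint distribution p(v, h) by direct enumeration of the
# energy E(v,h) = -v'Wh - a'h - b'v.
rbm_exact_joint <- function(rbm) {
  nv <- nrow(rbm$W); nh <- ncol(rbm$W)
  Vs <- all_binary(nv); Hs <- all_binary(nh)
  un <- matrix(0, nrow(Vs), nrow(Hs))
  for (i in seq_len(nrow(Vs))) for (j in seq_len(nrow(Hs))) {
    v <- Vs[i, ]; h <- Hs[j, ]
    un[i, j] <- exp(sum(v * (rbm$W %*% h)) + sum(rbm$a * h) + sum(rbm$b * v))
  }
  list(p = un / sum(un), Vs = Vs, Hs = Hs)
}

# Exact log-likelihood gradient wrt W for data rows V0:
#   E_data[v_i p(h_j|v)] - E_model[v_i h_j]
rbm_exact_gradient <- function(rbm, V0) {
  ph <- hidden_given_visible(rbm, V0)
  pos <- crossprod(V0, ph) / nrow(V0)
  ex <- rbm_exact_joint(rbm)
  neg <- matrix(0, nrow(rbm$W), ncol(rbm$W))
  for (i in seq_len(nrow(ex$Vs))) for (j in seq_len(nrow(ex$Hs))) {
    neg <- neg + ex$p[i, j] * outer(ex$Vs[i, ], ex$Hs[j, ])
  }
  pos - neg
}
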