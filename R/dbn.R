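#' Numerically stable logistic (sigmoid) function
#'
#' `g(x) = 1 / (1 + exp(-x))`, evaluated branch-wise so it neither
#' overflows nor underflows for `|x|` up to (and well beyond) 700. Accepts
#' vectors and matrices, preserving shape.
#'
#' @param x finite numeric vector or matrix.
#' @return values in `(0, 1)` (reaching 0/1 only at double precision).
#' @export
#' @examples
#' sigmoid(0)    # 0.5
#' sigmoid(500)  # 1 without overflow
sigmoid <- function(x) {
  # delegate to the C-level logistic CDF: stable on both tails and fast
  # on the matrix-heavy inner loops; dim attributes are preserved
  stats::plogis(x)
}

# Unvalidated conditionals for hot training loops (the exported versions
# validate and then do exactly this). Bias addition exploits column-major
# recycling instead of sweep().
hgv <- function(rbm, V) sigmoid(V %*% rbm$W + rep(rbm$a, each = nrow(V)))
vgh <- function(rbm, h) sigmoid(tcrossprod(h, rbm$W) + rep(rbm$b, each = nrow(h)))

#' Construct a restricted Boltzmann machine
#'
#' A bipartite energy model with `visible_dim` visible and `hidden_dim`
#' hidden units: symmetric weights `W` (visible x hidden), hidden biases
#' `a` and visible biases `b`. Weights are initialized as small seeded
#' Gaussians (sd 0.1), biases at zero.
#'
#' @param visible_dim,hidden_dim positive integers.
#' @param seed integer seed for the weight initialization.
#' @return object of class `rbm`.
#' @export
rbm_new <- function(visible_dim, hidden_dim, seed = 1L) {
  stopifnot(visible_dim >= 1L, hidden_dim >= 1L)
  W <- with_seed(seed, matrix(stats::rnorm(visible_dim * hidden_dim, sd = 0.1),
                              visible_dim, hidden_dim))
  structure(list(W = W, a = numeric(hidden_dim), b = numeric(visible_dim)),
            class = "rbm")
}

check_rbm <- function(rbm) {
  stopifnot(inherits(rbm, "rbm"))
  if (!all(is.finite(rbm$W), is.finite(rbm$a), is.finite(rbm$b))) {
    stopf("RBM parameters contain non-finite values")
  }
  invisible(rbm)
}

as_row_matrix <- function(V, dim_needed, what) {
  if (is.null(dim(V))) V <- matrix(V, nrow = 1L)
  if (ncol(V) != dim_needed) {
    stopf("%s has %d columns, expected %d", what, ncol(V), dim_needed)
  }
  V
}

#' Conditional hidden-unit probabilities P(h_j = 1 | V)
#'
#' `g(V W + a)` row-wise: the mean-field activation of each hidden unit
#' given the visible vector(s).
#'
#' @param rbm an [rbm_new()] object.
#' @param V visible vector of length `visible_dim`, or a matrix with one
#'   visible configuration per row.
#' @return matrix of probabilities in `(0, 1)`, one row per input row.
#' @export
hidden_given_visible <- function(rbm, V) {
  check_rbm(rbm)
  V <- as_row_matrix(V, nrow(rbm$W), "visible input")
  hgv(rbm, V)
}

#' Conditional visible-unit probabilities P(V_i = 1 | h)
#'
#' Mirror of [hidden_given_visible()] with the transposed weights and the
#' visible biases: `g(h W' + b)`.
#'
#' @param rbm an [rbm_new()] object.
#' @param h hidden vector of length `hidden_dim`, or a matrix row-wise.
#' @return matrix of probabilities in `(0, 1)`.
#' @export
visible_given_hidden <- function(rbm, h) {
  check_rbm(rbm)
  h <- as_row_matrix(h, ncol(rbm$W), "hidden input")
  vgh(rbm, h)
}

# One CD-k gradient estimate from a batch of visible rows V0, using the
# current RNG stream. Hidden states are sampled by thresholded uniform
# draws; the data-side hidden term uses probabilities, and by default so
# do the visible reconstructions (Hinton's practical recipe, which
# Rao-Blackwellizes the visible draw and lowers estimator variance).
# `sample_visible = TRUE` gives the fully-sampled textbook estimator,
# whose mean is compared against the exact log-likelihood gradient in
# the enumeration-oracle tests. Returns the ascent direction for the
# log-likelihood (positive phase minus negative phase).
rbm_cd_gradient <- function(rbm, V0, cd_steps = 1L, sample_visible = FALSE) {
  V0 <- as_row_matrix(V0, nrow(rbm$W), "batch")
  nb <- nrow(V0)
  ph0 <- hgv(rbm, V0)
  h <- (matrix(stats::runif(length(ph0)), nrow(ph0), ncol(ph0)) < ph0) * 1
  v <- V0
  for (s in seq_len(cd_steps)) {
    v <- vgh(rbm, h)
    if (sample_visible) {
      v <- (matrix(stats::runif(length(v)), nrow(v), ncol(v)) < v) * 1
    }
    ph <- hgv(rbm, v)
    if (s < cd_steps) {
      h <- (matrix(stats::runif(length(ph)), nrow(ph), ncol(ph)) < ph) * 1
    }
  }
  list(dW = (crossprod(V0, ph0) - crossprod(v, ph)) / nb,
       da = colMeans(ph0) - colMeans(ph),
       db = colMeans(V0) - colMeans(v),
       recon = v)
}

#' Train an RBM by contrastive divergence
#'
#' Mini-batch CD-k: for each batch the hidden layer is sampled from the
#' data, the visible layer reconstructed, and the difference of the
#' data-side and reconstruction-side visible-hidden correlations drives
#' the update of the weights; hidden and visible biases are updated from
#' the corresponding marginal differences. Deterministic given `seed`
#' (batch order and all Gibbs draws come from one seeded stream).
#'
#' @param rbm an [rbm_new()] object.
#' @param data matrix with `visible_dim` columns; entries in `[0, 1]`
#'   (probabilities or binary indicators).
#' @param epochs,learning_rate,batch_size,cd_steps training
#'   hyperparameters; defaults CD-1, rate 0.1, batches of 10, 100 epochs.
#' @param seed integer.
#' @return the trained `rbm`, with a `data.frame` of per-epoch mean squared
#'   reconstruction error attached as `attr(, "training_log")`.
#' @export
cd_train_rbm <- function(rbm, data, epochs = 100L, learning_rate = 0.1,
                         batch_size = 10L, cd_steps = 1L, seed = 1L) {
  check_rbm(rbm)
  data <- as_row_matrix(data, nrow(rbm$W), "training data")
  n <- nrow(data)
  if (n == 0L) stopf("empty training data")
  log_err <- numeric(epochs)
  rbm <- with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      errs <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        g <- rbm_cd_gradient(rbm, data[idx, , drop = FALSE], cd_steps)
        if (!all(is.finite(g$dW), is.finite(g$da), is.finite(g$db))) {
          stopf("non-finite CD update at epoch %d, batch starting %d", ep, s)
        }
        rbm$W <- rbm$W + learning_rate * g$dW
        rbm$a <- rbm$a + learning_rate * g$da
        rbm$b <- rbm$b + learning_rate * g$db
        errs <- errs + sum((data[idx, , drop = FALSE] - g$recon)^2)
      }
      log_err[ep] <- errs / (n * nrow(rbm$W))
    }
    rbm
  })
  attr(rbm, "training_log") <- data.frame(epoch = seq_len(epochs),
                                          reconstruction_error = log_err)
  rbm
}

#' Run an alternating Gibbs chain on an RBM
#'
#' Samples both layers (hidden from the visible conditional, then visible
#' from the hidden conditional) for `steps` iterations starting from `v0`.
#' Used by the enumeration oracle tests to check that the chain's
#' stationary distribution matches the Boltzmann distribution of the
#' energy model.
#'
#' @param rbm an [rbm_new()] object.
#' @param v0 binary visible start vector.
#' @param steps chain length.
#' @param seed integer.
#' @return list of integer matrices `v` (`steps x visible_dim`) and `h`
#'   (`steps x hidden_dim`), the sampled states after each full step.
#' @export
rbm_gibbs_chain <- function(rbm, v0, steps, seed = 1L) {
  check_rbm(rbm)
  nv <- nrow(rbm$W); nh <- ncol(rbm$W)
  v <- as_row_matrix(v0, nv, "v0")
  with_seed(seed, {
    vs <- matrix(0L, steps, nv); hs <- matrix(0L, steps, nh)
    for (t in seq_len(steps)) {
      ph <- hidden_given_visible(rbm, v)
      h <- (stats::runif(nh) < ph) * 1
      pv <- visible_given_hidden(rbm, h)
      v <- (stats::runif(nv) < pv) * 1
      vs[t, ] <- v; hs[t, ] <- h
    }
    list(v = vs, h = hs)
  })
}

#' Greedy layer-wise pretraining of a deep belief network
#'
#' Trains a stack of RBMs bottom-up: the first RBM sees the `k`-dimensional
#' reduced samples; each subsequent RBM is trained on the hidden
#' probabilities of the layer below (mean-field, no sampling between
#' layers). A supervised sigmoid head (used only during fine-tuning) is
#' initialized at the same time so that a zero-epoch fine-tune leaves the
#' model bit-identical.
#'
#' @param X matrix `n x k` of training inputs in `[0, 1]`.
#' @param hidden_sizes integer vector of hidden-layer widths; the default
#'   `c(10, 4)` gives the two-layer architecture `k -> 10 -> 4`, whose
#'   final width 4 is the extracted feature count.
#' @param epochs,learning_rate,batch_size,cd_steps per-layer CD training
#'   hyperparameters (see [cd_train_rbm()]).
#' @param seed integer; layer `l` trains with seed `seed + l`.
#' @return object of class `dbn_model`: list with `rbms`, `head`
#'   (list `w`, `b`), `layer_sizes` and `training_log`.
#' @export
dbn_pretrain <- function(X, hidden_sizes = c(10L, 4L), epochs = 100L,
                         learning_rate = 0.1, batch_size = 10L, cd_steps = 1L,
                         seed = 1L) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  layer_sizes <- c(ncol(X), as.integer(hidden_sizes))
  rbms <- vector("list", length(hidden_sizes))
  logs <- list()
  rep_cur <- X
  for (l in seq_along(hidden_sizes)) {
    rbm <- rbm_new(layer_sizes[l], layer_sizes[l + 1L], seed = derive_seed(seed, 10L * l))
    rbm <- cd_train_rbm(rbm, rep_cur, epochs = epochs,
                        learning_rate = learning_rate, batch_size = batch_size,
                        cd_steps = cd_steps, seed = derive_seed(seed, 10L * l + 1L))
    lg <- attr(rbm, "training_log")
    lg$layer <- l
    logs[[l]] <- lg
    attr(rbm, "training_log") <- NULL
    rbms[[l]] <- rbm
    rep_cur <- hidden_given_visible(rbm, rep_cur)
  }
  head_w <- with_seed(derive_seed(seed, 999L),
                      stats::rnorm(utils::tail(layer_sizes, 1L), sd = 0.1))
  structure(list(rbms = rbms, head = list(w = head_w, b = 0),
                 layer_sizes = layer_sizes,
                 training_log = do.call(rbind, logs)),
            class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  cat(sprintf("<dbn_model> layers %s%s\n", paste(x$layer_sizes, collapse = " -> "),
              if (isTRUE(attr(x, "finetuned"))) ", fine-tuned" else ""))
  invisible(x)
}

# Mean-field forward pass through every RBM layer; returns the list of
# layer activations (first element = input).
dbn_forward <- function(model, X) {
  acts <- list(X)
  for (l in seq_along(model$rbms)) {
    acts[[l + 1L]] <- hgv(model$rbms[[l]], acts[[l]])
  }
  acts
}

# Training cross-entropy of the sigmoid head on (X, y).
dbn_loss <- function(model, X, y) {
  acts <- dbn_forward(model, X)
  z <- as.vector(utils::tail(acts, 1L)[[1L]] %*% model$head$w) + model$head$b
  p <- sigmoid(z)
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# Analytic gradients of the cross-entropy with respect to every layer's
# weights/hidden biases and the head (full batch); the loss at the
# current parameters comes along for free from the same forward pass.
dbn_gradients <- function(model, X, y) {
  acts <- dbn_forward(model, X)
  n <- nrow(acts[[1L]])
  top <- utils::tail(acts, 1L)[[1L]]
  p <- sigmoid(as.vector(top %*% model$head$w) + model$head$b)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  delta <- matrix((p - y) / n, ncol = 1L)
  g_head_w <- as.vector(crossprod(top, delta))
  g_head_b <- sum(delta)
  delta_l <- (delta %*% matrix(model$head$w, nrow = 1L)) * top * (1 - top)
  gW <- vector("list", length(model$rbms))
  ga <- vector("list", length(model$rbms))
  for (l in rev(seq_along(model$rbms))) {
    gW[[l]] <- crossprod(acts[[l]], delta_l)
    ga[[l]] <- colSums(delta_l)
    if (l > 1L) {
      a <- acts[[l]]
      delta_l <- tcrossprod(delta_l, model$rbms[[l]]$W) * a * (1 - a)
    }
  }
  list(W = gW, a = ga, head_w = g_head_w, head_b = g_head_b, loss = loss)
}

#' Supervised fine-tuning of a pretrained belief network
#'
#' Attaches the single-unit sigmoid head initialized at pretraining time
#' and runs full-batch gradient descent with classical momentum on the
#' binary cross-entropy, back-propagating the error through every RBM
#' layer (updating layer weights and hidden biases; visible biases play
#' no role in the forward pass and are left untouched). The head itself
#' is discarded downstream: only the top hidden activations are exported
#' as features.
#'
#' @param model a pretrained `dbn_model`.
#' @param X training inputs `n x k` in `[0, 1]`.
#' @param y binary labels in `{0, 1}`.
#' @param epochs,learning_rate,momentum heavy-ball gradient-descent
#'   hyperparameters (defaults 1000 epochs, rate 0.5, momentum 0.9 —
#'   full-batch steps are mean gradients and need the larger rate;
#'   see the methods vignette). `epochs = 0` returns the model unchanged.
#' @param seed accepted for interface symmetry; fine-tuning is
#'   deterministic (full batch), so it is unused.
#' @return the fine-tuned `dbn_model`; per-epoch cross-entropy appended to
#'   `training_log` as rows with `layer = NA`.
#' @export
dbn_finetune <- function(model, X, y, epochs = 1000L, learning_rate = 0.5,
                         momentum = 0.9, seed = 1L) {
  stopifnot(inherits(model, "dbn_model"))
  if (!is_binary01(as.numeric(y))) stopf("labels must be 0/1")
  y <- as.numeric(y)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (epochs == 0L) return(model)
  losses <- numeric(epochs)
  velW <- lapply(model$rbms, function(r) r$W * 0)
  vela <- lapply(model$rbms, function(r) r$a * 0)
  vel_hw <- model$head$w * 0
  vel_hb <- 0
  for (ep in seq_len(epochs)) {
    g <- dbn_gradients(model, X, y)
    for (l in seq_along(model$rbms)) {
      velW[[l]] <- momentum * velW[[l]] - learning_rate * g$W[[l]]
      vela[[l]] <- momentum * vela[[l]] - learning_rate * g$a[[l]]
      model$rbms[[l]]$W <- model$rbms[[l]]$W + velW[[l]]
      model$rbms[[l]]$a <- model$rbms[[l]]$a + vela[[l]]
    }
    vel_hw <- momentum * vel_hw - learning_rate * g$head_w
    vel_hb <- momentum * vel_hb - learning_rate * g$head_b
    model$head$w <- model$head$w + vel_hw
    model$head$b <- model$head$b + vel_hb
    losses[ep] <- g$loss  # loss at the pre-step parameters of this epoch
  }
  model$training_log <- rbind(model$training_log,
                              data.frame(epoch = seq_len(epochs),
                                         reconstruction_error = losses,
                                         layer = NA_integer_))
  attr(model, "finetuned") <- TRUE
  model
}

#' Extract belief-network features
#'
#' Deterministic mean-field forward pass: each layer emits its hidden
#' probabilities (no sampling), and the final hidden layer — width 4 under
#' the default architecture — is returned as the feature matrix fed to the
#' classifier.
#'
#' @param model trained `dbn_model`.
#' @param X matrix `n x k` with `k = model$layer_sizes[1]`.
#' @return matrix `n x final_hidden_dim` with entries in `(0, 1)`.
#' @export
dbn_transform <- function(model, X) {
  stopifnot(inherits(model, "dbn_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$layer_sizes[1L]) {
    stopf("input has %d columns, model expects %d", ncol(X), model$layer_sizes[1L])
  }
  utils::tail(dbn_forward(model, X), 1L)[[1L]]
}

#' Save / load a belief network
#'
#' Plain-JSON archive of all layer weights, biases and the head.
#'
#' @param model `dbn_model`.
#' @param path file path.
#' @export
write_dbn_model <- function(model, path) {
  stopifnot(inherits(model, "dbn_model"))
  jsonlite::write_json(
    list(rbms = lapply(model$rbms, function(r) list(W = r$W, a = r$a, b = r$b)),
         head = model$head, layer_sizes = model$layer_sizes,
         finetuned = isTRUE(attr(model, "finetuned"))),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_dbn_model
#' @export
read_dbn_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rbms <- lapply(raw$rbms, function(r) {
    structure(list(W = r$W, a = as.numeric(r$a), b = as.numeric(r$b)), class = "rbm")
  })
  out <- structure(list(rbms = rbms,
                        head = list(w = as.numeric(raw$head$w), b = raw$head$b),
                        layer_sizes = as.integer(raw$layer_sizes),
                        training_log = NULL),
                   class = "dbn_model")
  attr(out, "finetuned") <- isTRUE(raw$finetuned)
  out
}
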