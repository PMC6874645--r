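test_that("sigmoid is exact at anchors and stable at extremes", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  # antisymmetry identity over a wide range
  x <- seq(-30, 30, length.out = 101)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 101), tolerance = 1e-12)
  # no overflow on either branch
  expect_identical(sigmoid(500), 1)
  expect_equal(sigmoid(-500), exp(-500) / (1 + exp(-500)), tolerance = 1e-12)
  expect_gt(sigmoid(-500), 0)  # the far tail keeps its tiny mass
  expect_false(any(is.nan(sigmoid(c(-750, 750)))))
  # matrix shape preserved
  expect_identical(dim(sigmoid(matrix(0, 2, 3))), c(2L, 3L))
})

test_that("conditional probabilities match hand evaluation", {
  rbm <- rbm_new(2, 1, seed = 1)
  rbm$W[] <- 1; rbm$a[] <- 0; rbm$b[] <- 0
  expect_equal(as.vector(hidden_given_visible(rbm, c(1, 1))), sigmoid(2),
               tolerance = 1e-12)  # g(2) = 0.8808
  # zero parameters give 0.5 everywhere
  z <- rbm_new(3, 2, seed = 1); z$W[] <- 0
  expect_equal(as.vector(hidden_given_visible(z, c(1, 0, 1))), c(0.5, 0.5))
  expect_equal(as.vector(visible_given_hidden(z, c(1, 0))), rep(0.5, 3))
  # mirror path uses W (not W') and bias b: check a symmetric toy by hand
  rbm$b <- c(0.5, -0.5)
  expect_equal(as.vector(visible_given_hidden(rbm, 1)),
               c(sigmoid(1.5), sigmoid(0.5)), tolerance = 1e-12)
  expect_error(hidden_given_visible(rbm, c(1, 1, 1)), "columns")
  expect_error(visible_given_hidden(rbm, c(1, 1, 1)), "columns")
  # probabilities always land strictly inside (0, 1) for finite params
  r <- rbm_new(4, 3, seed = 9)
  p <- hidden_given_visible(r, matrix(stats::runif(20), 5, 4))
  expect_true(all(p > 0 & p < 1))
})

test_that("contrastive divergence learns a repeated pattern", {
  pattern <- matrix(rep(c(1, 0, 1), 50), ncol = 3, byrow = TRUE)
  rbm <- rbm_new(3, 2, seed = 2)
  trained <- cd_train_rbm(rbm, pattern, epochs = 200, seed = 3)
  log <- attr(trained, "training_log")
  expect_identical(nrow(log), 200L)
  expect_lt(mean(tail(log$reconstruction_error, 10)),
            log$reconstruction_error[1])
  # zero learning rate leaves parameters untouched
  frozen <- cd_train_rbm(rbm, pattern, epochs = 3, learning_rate = 0, seed = 3)
  expect_identical(frozen$W, rbm$W)
  expect_identical(frozen$a, rbm$a)
  expect_identical(frozen$b, rbm$b)
})

test_that("CD-1 gradient agrees with the exact enumeration oracle", {
  # 2 visible x 2 hidden: the full joint has 16 states, so the exact
  # log-likelihood gradient is computable by enumeration.
  # The comparison uses the fully-sampled estimator: near initialization
  # the CD-1 bias is far below the Monte-Carlo standard error, so the
  # mean must land within 3 SE of the exact gradient. Batch rows are
  # sampled independently, so batch replication yields many draws per
  # call (block means give the SE).
  rbm <- rbm_new(2, 2, seed = 4)
  V0 <- rbind(c(1, 0), c(0, 1), c(1, 1))
  exact <- rbm_exact_gradient(rbm, V0)
  big <- V0[rep(1:3, times = 200), ]
  blocks <- ecpredict:::with_seed(5, {
    replicate(20, ecpredict:::rbm_cd_gradient(rbm, big, sample_visible = TRUE)$dW)
  })
  est <- apply(blocks, c(1, 2), mean)
  se <- apply(blocks, c(1, 2), stats::sd) / sqrt(dim(blocks)[3])
  expect_true(all(abs(est - exact) <= 3 * se))
})

test_that("alternating Gibbs sampling reaches the Boltzmann distribution", {
  rbm <- rbm_new(3, 2, seed = 6)
  ex <- rbm_exact_joint(rbm)
  chain <- rbm_gibbs_chain(rbm, c(0, 0, 0), steps = 20000, seed = 7)
  # empirical joint distribution over the 32 (v, h) states
  code <- chain$v %*% c(1, 2, 4) + chain$h %*% c(8, 16) + 1
  emp <- tabulate(code, nbins = 32) / nrow(chain$v)
  exact <- numeric(32)
  for (i in 1:8) for (j in 1:4) {
    exact[(i - 1) + (j - 1) * 8 + 1] <- ex$p[i, j]
  }
  tv <- 0.5 * sum(abs(emp - exact))
  expect_lt(tv, 0.05)
})

test_that("greedy pretraining stacks layers with chained dimensions", {
  X <- ecpredict:::with_seed(8, matrix(stats::runif(40 * 14), 40, 14))
  dbn <- dbn_pretrain(X, hidden_sizes = c(10, 4), epochs = 5, seed = 9)
  expect_identical(dim(dbn$rbms[[1]]$W), c(14L, 10L))
  expect_identical(dim(dbn$rbms[[2]]$W), c(10L, 4L))
  expect_identical(dbn$layer_sizes, c(14L, 10L, 4L))
  expect_identical(dim(dbn_transform(dbn, X)), c(40L, 4L))

  # a one-layer stack is exactly one CD training run
  one <- dbn_pretrain(X, hidden_sizes = 6, epochs = 5, seed = 9)
  solo <- cd_train_rbm(rbm_new(14, 6, seed = ecpredict:::derive_seed(9, 10)),
                       X, epochs = 5, seed = ecpredict:::derive_seed(9, 11))
  expect_identical(one$rbms[[1]]$W, solo$W)
  expect_identical(one$rbms[[1]]$a, solo$a)
})

test_that("transform is a deterministic row-wise mean-field pass", {
  X <- ecpredict:::with_seed(10, matrix(stats::runif(20 * 6), 20, 6))
  dbn <- dbn_pretrain(X, hidden_sizes = c(5, 4), epochs = 3, seed = 11)
  X2 <- dbn_transform(dbn, X)
  expect_true(all(X2 > 0 & X2 < 1))
  expect_identical(dbn_transform(dbn, X), X2)  # no sampling at transform time
  # batch concatenation = concatenation of batches (row independence)
  expect_identical(rbind(dbn_transform(dbn, X[1:7, ]), dbn_transform(dbn, X[8:20, ])), X2)
  # zero-weight model maps everything to 0.5
  z <- dbn
  for (l in 1:2) { z$rbms[[l]]$W[] <- 0; z$rbms[[l]]$a[] <- 0 }
  expect_true(all(dbn_transform(z, X) == 0.5))
  expect_error(dbn_transform(dbn, X[, 1:3]), "expects")
})

test_that("fine-tuning reduces training cross-entropy on separable data", {
  set.seed(12)
  X <- rbind(matrix(stats::runif(30 * 5, 0, 0.35), 30, 5),
             matrix(stats::runif(30 * 5, 0.65, 1), 30, 5))
  y <- rep(c(0, 1), each = 30)
  dbn <- dbn_pretrain(X, hidden_sizes = c(6, 4), epochs = 10, seed = 13)
  before <- ecpredict:::dbn_loss(dbn, X, y)
  ft <- dbn_finetune(dbn, X, y, epochs = 100)
  after <- ecpredict:::dbn_loss(ft, X, y)
  expect_lt(after, 0.9 * before)    # >= 10% reduction after 100 epochs
  # zero-epoch fine-tune is the identity
  expect_identical(dbn_finetune(dbn, X, y, epochs = 0), dbn)
  expect_error(dbn_finetune(dbn, X, c(y[-1], 2)), "0/1")
})

test_that("analytic gradients match central finite differences", {
  set.seed(14)
  X <- matrix(stats::runif(3 * 5), 3, 5)
  y <- c(1, 0, 1)
  dbn <- dbn_pretrain(X, hidden_sizes = c(4, 3), epochs = 2, seed = 15)
  g <- ecpredict:::dbn_gradients(dbn, X, y)
  h <- 1e-6
  # head weights
  for (i in seq_along(dbn$head$w)) {
    up <- dbn; up$head$w[i] <- up$head$w[i] + h
    dn <- dbn; dn$head$w[i] <- dn$head$w[i] - h
    fd <- (ecpredict:::dbn_loss(up, X, y) - ecpredict:::dbn_loss(dn, X, y)) / (2 * h)
    expect_equal(g$head_w[i], fd, tolerance = 1e-5)
  }
  # a few first-layer weights (checks the full backprop chain)
  for (idx in list(c(1, 1), c(3, 2), c(5, 4))) {
    up <- dbn; up$rbms[[1]]$W[idx[1], idx[2]] <- up$rbms[[1]]$W[idx[1], idx[2]] + h
    dn <- dbn; dn$rbms[[1]]$W[idx[1], idx[2]] <- dn$rbms[[1]]$W[idx[1], idx[2]] - h
    fd <- (ecpredict:::dbn_loss(up, X, y) - ecpredict:::dbn_loss(dn, X, y)) / (2 * h)
    expect_equal(g$W[[1]][idx[1], idx[2]], fd, tolerance = 1e-5)
  }
})

test_that("belief networks archive and restore losslessly", {
  X <- ecpredict:::with_seed(16, matrix(stats::runif(10 * 4), 10, 4))
  dbn <- dbn_finetune(dbn_pretrain(X, c(3, 2), epochs = 2, seed = 17),
                      X, rep(c(0, 1), 5), epochs = 5)
  p <- file.path(withr::local_tempdir(), "dbn.json")
  write_dbn_model(dbn, p)
  d2 <- read_dbn_model(p)
  expect_equal(dbn_transform(d2, X), dbn_transform(dbn, X), tolerance = 1e-12)
})
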