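test_that("two-point hard-margin case matches the analytic solution", {
  fit <- svm_fit(rbind(c(1, 1), c(-1, -1)), c(1, 0), C = Inf)
  expect_equal(fit$w, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(svm_margin(fit), 2 * sqrt(2), tolerance = 1e-6)
  expect_equal(fit$alpha, c(0.25, 0.25), tolerance = 1e-6)
})

test_that("KKT conditions hold at every fit", {
  for (s in 1:4) {
    sep <- separable_2d(n = 16, seed = s)
    for (C in c(1, 100, Inf)) {
      fit <- svm_fit(sep$X, sep$y, C = C, tol = 1e-8)
      ys <- ifelse(sep$y == 1, 1, -1)
      expect_lt(abs(sum(fit$alpha * ys)), 1e-8)                       # equality constraint
      expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= C + 1e-8))   # box
      expect_equal(fit$w, as.vector(crossprod(sep$X, fit$alpha * ys)),
                   tolerance = 1e-8)                                  # stationarity
      # hard margin: support vectors sit on the margin, train error 0
      if (is.infinite(C)) {
        marg <- ys * (sep$X %*% fit$w + fit$b)
        expect_true(all(abs(marg[fit$support_idx] - 1) < 1e-6))
        expect_true(all(marg >= 1 - 1e-6))
        expect_equal(svm_predict(fit, sep$X), sep$y)
      }
    }
  }
})

test_that("dual objective matches the geometric enumeration oracle", {
  for (s in 1:6) {
    sep <- separable_2d(n = 20, seed = 100 + s)
    fit <- svm_fit(sep$X, sep$y, C = Inf, tol = 1e-6)
    oracle <- svm_oracle_2d(sep$X, sep$y)
    expect_equal(0.5 * sum(fit$w^2), oracle$objective, tolerance = 1e-4)
    # at the optimum the dual objective equals -||w||^2 / 2
    expect_equal(fit$dual_objective, -oracle$objective, tolerance = 1e-4)
  }
})

test_that("duplicating the training set leaves the solution unchanged", {
  sep <- separable_2d(n = 14, seed = 42)
  f1 <- svm_fit(sep$X, sep$y, C = Inf, tol = 1e-6)
  f2 <- svm_fit(rbind(sep$X, sep$X), c(sep$y, sep$y), C = Inf, tol = 1e-6)
  expect_equal(f2$w, f1$w, tolerance = 1e-4)
  expect_equal(f2$b, f1$b, tolerance = 1e-4)
})

test_that("prediction follows the sign rule with positive ties", {
  model <- structure(list(w = c(1, 0), b = 0, alpha = numeric(2),
                          support_idx = integer(0), C = 1,
                          dual_objective = 0, converged = TRUE),
                     class = "svm_model")
  expect_equal(svm_predict(model, c(2, 0)), 1)
  expect_equal(svm_predict(model, c(-2, 5)), 0)
  expect_equal(svm_predict(model, c(0, 3)), 1)   # on the hyperplane -> positive
  expect_error(svm_predict(model, matrix(1, 1, 3)), "mismatch")
  # scale invariance of the decision under joint positive rescaling
  scaled <- model; scaled$w <- model$w * 7; scaled$b <- model$b * 7
  Xr <- matrix(stats::rnorm(40), 20, 2)
  expect_equal(svm_predict(scaled, Xr), svm_predict(model, Xr))
})

test_that("margin is 2/||w|| and scales inversely with w", {
  m <- structure(list(w = c(2, 0), b = 0), class = "svm_model")
  expect_equal(svm_margin(m), 1)
  m$w <- c(0.5, 0.5)
  expect_equal(svm_margin(m), 2 / sqrt(0.5), tolerance = 1e-12)
  m2 <- m; m2$w <- m$w * 3
  expect_equal(svm_margin(m2), svm_margin(m) / 3, tolerance = 1e-12)
  m$w <- c(0, 0)
  expect_error(svm_margin(m), "zero weight")
})

test_that("degenerate training sets are rejected", {
  expect_error(svm_fit(matrix(1:4, 2, 2), c(1, 1)), "single class")
  expect_error(svm_fit(matrix(1, 1, 2), 1), "at least 2")
})

test_that("fitted models archive and restore losslessly", {
  sep <- separable_2d(n = 10, seed = 3)
  fit <- svm_fit(sep$X, sep$y, C = Inf)
  p <- file.path(withr::local_tempdir(), "svm.json")
  write_svm_model(fit, p)
  f2 <- read_svm_model(p)
  expect_equal(f2$w, fit$w, tolerance = 1e-12)
  expect_identical(f2$C, Inf)
  expect_equal(svm_predict(f2, sep$X), svm_predict(fit, sep$X))
})
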