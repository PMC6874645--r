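test_that("exact rank-1 matrices are reconstructed essentially exactly", {
  u <- c(1, 2, 3, 4); v <- c(2, 1, 3)
  X <- outer(u, v)
  m <- nmf_factorize(X, k = 1, seed = 1)
  expect_lt(norm(X - m$W %*% m$H, "F") / norm(X, "F"), 1e-6)
  expect_identical(dim(m$W), c(4L, 1L))
  expect_identical(dim(m$H), c(1L, 3L))
})

test_that("input validation names the offending cell and range", {
  X <- matrix(1, 3, 3); X[2, 3] <- -0.1
  expect_error(nmf_factorize(X, 2), "row 2, column 3")
  expect_error(nmf_factorize(matrix(1, 3, 3), 4), "out of range")
  expect_error(nmf_factorize(matrix(1, 3, 3), 0), "out of range")
  # compression condition (n + m) k < n m only when requested
  expect_error(nmf_factorize(matrix(1, 2, 2), 2, enforce_compression = TRUE),
               "compress")
  expect_silent(nmf_factorize(matrix(1, 2, 2), 2, restarts = 1, max_iter = 5))
})

test_that("objective trace is non-increasing and factors stay nonnegative", {
  for (s in 1:3) {
    X <- ecpredict:::with_seed(s, matrix(stats::runif(20 * 8), 20, 8))
    m <- nmf_factorize(X, k = 3, max_iter = 200, tol = 0, restarts = 2, seed = s)
    expect_true(all(diff(m$objective_trace) <= 1e-9))
    expect_true(all(m$W >= 0))
    expect_true(all(m$H >= 0))
  }
})

test_that("requested latent dimension drives the factor shapes", {
  X <- ecpredict:::with_seed(2, matrix(stats::runif(30 * 50), 30, 50))
  m <- nmf_factorize(X, k = 14, max_iter = 50, restarts = 1, seed = 2)
  expect_identical(dim(m$W), c(30L, 14L))
  expect_identical(dim(m$H), c(14L, 50L))
})

test_that("solver beats a large random search on the same objective", {
  X <- ecpredict:::with_seed(7, matrix(stats::runif(6 * 4), 6, 4))
  m <- nmf_factorize(X, k = 2, max_iter = 200, restarts = 2, seed = 7)
  f_fit <- tail(m$objective_trace, 1)
  # independent oracle: 10,000 random nonnegative (W, H) pairs
  f_rand <- ecpredict:::with_seed(99, {
    min(vapply(1:10000, function(i) {
      W <- matrix(stats::runif(6 * 2), 6, 2) * sqrt(mean(X) / 2)
      H <- matrix(stats::runif(2 * 4), 2, 4) * sqrt(mean(X) / 2)
      sum((X - W %*% H)^2)
    }, numeric(1)))
  })
  expect_lt(f_fit, f_rand)
})

test_that("identical seeds give bitwise-identical factorizations", {
  X <- ecpredict:::with_seed(11, matrix(stats::runif(15 * 6), 15, 6))
  m1 <- nmf_factorize(X, 3, max_iter = 80, seed = 123)
  m2 <- nmf_factorize(X, 3, max_iter = 80, seed = 123)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$H, m2$H)
  expect_identical(m1$objective_trace, m2$objective_trace)
})

test_that("row permutation equivariance holds under matched initialization", {
  X <- ecpredict:::with_seed(13, matrix(stats::runif(12 * 5), 12, 5))
  perm <- ecpredict:::with_seed(14, sample(12))
  W0 <- ecpredict:::with_seed(15, matrix(stats::runif(12 * 2), 12, 2))
  H0 <- ecpredict:::with_seed(16, matrix(stats::runif(2 * 5), 2, 5))
  m <- nmf_factorize(X, 2, max_iter = 100, init = list(W = W0, H = H0))
  mp <- nmf_factorize(X[perm, ], 2, max_iter = 100,
                      init = list(W = W0[perm, ], H = H0))
  expect_equal(mp$W, m$W[perm, ], tolerance = 1e-10)
  expect_equal(mp$H, m$H, tolerance = 1e-10)
})

test_that("held-out rows project onto H with comparable reconstruction error", {
  tab <- generate_samples(synthetic_config(n = 80, seed = 21))
  Xp <- preprocess_fit(tab)$Xp
  m <- nmf_factorize(Xp[1:60, ], 5, seed = 3)
  Wnew <- nmf_project(m, Xp[61:80, ], seed = 4)
  expect_true(all(Wnew >= 0))
  err_test <- norm(Xp[61:80, ] - Wnew %*% m$H, "F") / norm(Xp[61:80, ], "F")
  err_train <- norm(Xp[1:60, ] - m$W %*% m$H, "F") / norm(Xp[1:60, ], "F")
  expect_lt(err_test, 2.5 * err_train + 0.1)
})

test_that("feature weight report ranks and flags attributes correctly", {
  H <- rbind(c(0.1, 9, 0.2, 0.3), c(0.5, 0.1, 0.4, 0.2))
  model <- structure(list(W = matrix(1, 2, 2), H = H, k = 2L,
                          objective_trace = 1, seed = 1L, restart = 1L,
                          converged = TRUE), class = "nmf_model")
  rep <- feature_weight_report(model, paste0("attr", 1:4), top_fraction = 0.25)
  f1 <- rep[rep$feature_index == 1, ]
  expect_identical(f1$attribute_name[1], "attr2")   # dominant entry first
  expect_identical(f1$rank, 1:4)
  expect_true(all(diff(f1$weight) <= 0))
  expect_identical(sum(f1$top), 1L)

  rep_all <- feature_weight_report(model, paste0("attr", 1:4), top_fraction = 1)
  expect_true(all(rep_all$top))                      # full listing
  expect_identical(nrow(rep_all), 8L)
  expect_error(feature_weight_report(model, paste0("attr", 1:4), 0), "top_fraction")
})

test_that("planted driving attributes surface at the top of the report", {
  # features 1-5 load on the planted factor; the rest is weak noise
  hits <- vapply(1:10, function(s) {
    X <- ecpredict:::with_seed(s, {
      u <- stats::rgamma(40, 2, 2)
      v <- c(stats::runif(5, 2, 3), rep(0, 10))
      pmax(outer(u, v) + matrix(stats::rnorm(40 * 15, sd = 0.1), 40, 15), 0)
    })
    m <- nmf_factorize(X, 1, seed = s)
    rep <- feature_weight_report(m, paste0("a", 1:15), top_fraction = 1 / 3)
    top5 <- rep$attribute_name[rep$rank <= 5]
    all(top5 %in% paste0("a", 1:5))
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("factorizations archive and restore losslessly", {
  X <- ecpredict:::with_seed(31, matrix(stats::runif(10 * 6), 10, 6))
  m <- nmf_factorize(X, 2, max_iter = 60, seed = 5)
  p <- file.path(withr::local_tempdir(), "nmf.json")
  write_nmf_model(m, p)
  m2 <- read_nmf_model(p)
  expect_equal(m2$W, m$W, tolerance = 1e-12)
  expect_equal(m2$H, m$H, tolerance = 1e-12)
  expect_identical(m2$k, m$k)
})
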