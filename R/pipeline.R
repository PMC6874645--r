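#' Pipeline configuration
#'
#' Collects every tunable of the four-stage pipeline with its default.
#' Defaults follow the source protocol where it states one (latent
#' dimension 14, two hidden layers ending in 4 extracted features, 90/10
#' stratified splits averaged over 100 runs); training hyperparameters the
#' protocol leaves open (CD-1, learning rate 0.1, batch size 10, 100
#' epochs, SVM C = 1) are package defaults, all overridable.
#'
#' @param k latent dimension of the factorization stage (default 14).
#' @param hidden_sizes belief-network hidden widths; the last entry is the
#'   extracted feature count (default `c(10, 4)`).
#' @param pretrain_epochs,learning_rate,batch_size,cd_steps per-layer CD
#'   pretraining hyperparameters.
#' @param finetune_epochs,finetune_lr,momentum supervised fine-tuning
#'   hyperparameters (full-batch heavy-ball descent; defaults 1000
#'   epochs, rate 0.5, momentum 0.9).
#' @param svm_C soft-margin penalty (default 1; `Inf` = hard margin).
#' @param test_fraction held-out fraction per split (default 0.10).
#' @param n_runs number of repeated stratified splits to average
#'   (default 100).
#' @param seed master seed; per-run seeds are derived as `seed + run`.
#' @param strict_no_leakage if `TRUE`, the factorization is fitted on the
#'   training rows only and test rows are projected by nonnegative least
#'   squares; the default `FALSE` fits on the full matrix before
#'   splitting, exactly as the source protocol prescribes — note this
#'   leaks unlabeled test-row information into the representation.
#' @param standardize_binary passed to [preprocess_fit()].
#' @param nmf_max_iter,nmf_tol,nmf_restarts factorization solver settings.
#' @return list of class `ecp_config`.
#' @export
ecp_config <- function(k = 14L, hidden_sizes = c(10L, 4L),
                       pretrain_epochs = 100L, finetune_epochs = 1000L,
                       learning_rate = 0.1, finetune_lr = 0.5, momentum = 0.9,
                       batch_size = 10L, cd_steps = 1L,
                       svm_C = 1, test_fraction = 0.10, n_runs = 100L,
                       seed = 1L, strict_no_leakage = FALSE,
                       standardize_binary = TRUE,
                       nmf_max_iter = 500L, nmf_tol = 1e-6, nmf_restarts = 5L) {
  cfg <- list(k = as.integer(k), hidden_sizes = as.integer(hidden_sizes),
              pretrain_epochs = as.integer(pretrain_epochs),
              finetune_epochs = as.integer(finetune_epochs),
              learning_rate = learning_rate, finetune_lr = finetune_lr,
              momentum = momentum, batch_size = as.integer(batch_size),
              cd_steps = as.integer(cd_steps), svm_C = svm_C,
              test_fraction = test_fraction, n_runs = as.integer(n_runs),
              seed = as.integer(seed),
              strict_no_leakage = isTRUE(strict_no_leakage),
              standardize_binary = isTRUE(standardize_binary),
              nmf_max_iter = as.integer(nmf_max_iter), nmf_tol = nmf_tol,
              nmf_restarts = as.integer(nmf_restarts))
  if (cfg$k < 1L) config_error("k must be >= 1")
  if (cfg$test_fraction <= 0 || cfg$test_fraction >= 1) config_error("test_fraction must be in (0, 1)")
  if (cfg$n_runs < 1L) config_error("n_runs must be >= 1")
  if (any(cfg$hidden_sizes < 1L)) config_error("hidden_sizes must be positive")
  if (cfg$learning_rate <= 0) config_error("learning_rate must be positive")
  structure(cfg, class = "ecp_config")
}

#' Stratified train/test split
#'
#' Partitions samples into train and test sets class by class: within each
#' label class, `round((1 - test_fraction) * class_count)` samples are
#' drawn (without replacement, seeded) for training and the rest form the
#' test set, so both classes keep their share — e.g. 90 negatives and 10
#' positives at `test_fraction = 0.1` give exactly 81 + 9 training
#' samples.
#'
#' @param y binary labels in `{0, 1}`; each class needs at least 2
#'   members.
#' @param test_fraction held-out fraction in `(0, 1)`.
#' @param seed integer.
#' @return a [split_indices()] object.
#' @export
stratified_split <- function(y, test_fraction = 0.10, seed = 1L) {
  y <- as.numeric(y)
  if (!is_binary01(y)) config_error("labels must be 0/1")
  if (test_fraction <= 0 || test_fraction >= 1) config_error("test_fraction must be in (0, 1)")
  n <- length(y)
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < 2L)) {
    config_error("each class needs >= 2 samples (got %d negatives, %d positives)",
                 counts[1L], counts[2L])
  }
  train <- with_seed(seed, {
    unlist(lapply(c(0, 1), function(cl) {
      idx <- which(y == cl)
      n_train <- round((1 - test_fraction) * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)  # keep both sets populated
      idx[sample.int(length(idx), n_train)]
    }))
  })
  split_indices(train, setdiff(seq_len(n), train), n)
}

# Latent features handed to the belief network: columns of the NMF base
# matrix W min-max scaled to [0, 1] so they are valid visible-unit
# probabilities. Returns the scaled matrix plus the scaling parameters
# (reused to place projected test rows on the same scale in strict mode).
latent_features <- function(W, mins = NULL, ranges = NULL) {
  if (is.null(mins)) { mins <- apply(W, 2L, min); ranges <- apply(W, 2L, max) - mins }
  structure(list(X1 = minmax_apply(W, mins, ranges, clip = TRUE),
                 mins = mins, ranges = ranges), class = "latent_features")
}

# One stratified split plus everything downstream of the factorization:
# belief-network pretraining and fine-tuning on the training rows only,
# feature extraction for both partitions, SVM fit on train, metrics on
# test. `prep` is either a latent_features object (shared factorization)
# or a list with train/test matrices already separated (strict mode).
run_split <- function(prep, y, config, run_seed) {
  if (inherits(prep, "latent_features")) {
    sp <- stratified_split(y, config$test_fraction, seed = run_seed)
    X1_train <- prep$X1[sp$train_idx, , drop = FALSE]
    X1_test <- prep$X1[sp$test_idx, , drop = FALSE]
  } else {
    sp <- prep$split
    X1_train <- prep$X1_train
    X1_test <- prep$X1_test
  }
  y_train <- y[sp$train_idx]; y_test <- y[sp$test_idx]
  dbn <- dbn_pretrain(X1_train, hidden_sizes = config$hidden_sizes,
                      epochs = config$pretrain_epochs,
                      learning_rate = config$learning_rate,
                      batch_size = config$batch_size,
                      cd_steps = config$cd_steps,
                      seed = derive_seed(run_seed, 1L))
  dbn <- dbn_finetune(dbn, X1_train, y_train,
                      epochs = config$finetune_epochs,
                      learning_rate = config$finetune_lr,
                      momentum = config$momentum,
                      seed = derive_seed(run_seed, 2L))
  X2_train <- dbn_transform(dbn, X1_train)
  X2_test <- dbn_transform(dbn, X1_test)
  # Extracted features can sit on very different (often near-saturated)
  # scales per unit; standardize them on training statistics so the
  # margin penalty C acts on a comparable scale for every unit.
  mu2 <- colMeans(X2_train)
  sd2 <- apply(X2_train, 2L, stats::sd)
  sd2[sd2 < 1e-12] <- 1
  X2_train <- scale(X2_train, mu2, sd2)
  X2_test <- scale(X2_test, mu2, sd2)
  svm <- svm_fit(X2_train, y_train, C = config$svm_C,
                 seed = derive_seed(run_seed, 3L))
  y_pred <- svm_predict(svm, X2_test)
  list(metrics = compute_metrics(confusion(y_test, y_pred)),
       split = sp, dbn = dbn, svm = svm)
}

# Preprocess + factorize the full table once (the default, leaky protocol:
# the factorization sees all rows, labels see only the training rows).
prepare_full <- function(table, config) {
  pp <- preprocess_fit(table, standardize_binary = config$standardize_binary)
  model <- nmf_factorize(pp$Xp, config$k,
                         max_iter = config$nmf_max_iter, tol = config$nmf_tol,
                         restarts = config$nmf_restarts,
                         seed = derive_seed(config$seed, 0L))
  list(stats = pp$stats, nmf = model, latent = latent_features(model$W))
}

# Strict-mode preparation for one split: standardize and factorize on the
# training rows only, then project the held-out rows onto the fitted H.
prepare_strict <- function(table, config, sp) {
  Xtr <- table$X[sp$train_idx, , drop = FALSE]
  Xte <- table$X[sp$test_idx, , drop = FALSE]
  pp <- preprocess_fit(Xtr, standardize_binary = config$standardize_binary)
  model <- nmf_factorize(pp$Xp, config$k,
                         max_iter = config$nmf_max_iter, tol = config$nmf_tol,
                         restarts = config$nmf_restarts,
                         seed = derive_seed(config$seed, 0L))
  W_test <- nmf_project(model, preprocess_apply(Xte, pp$stats),
                        seed = derive_seed(config$seed, 7L))
  lf <- latent_features(model$W)
  list(split = sp,
       X1_train = lf$X1,
       X1_test = minmax_apply(W_test, lf$mins, lf$ranges, clip = TRUE),
       nmf = model)
}

#' Run the full pipeline on one stratified split
#'
#' Executes the four stages in order — standardization and nonnegativity
#' restoration, factorization, stratified 90/10 split, belief-network
#' feature extraction trained on the training partition, linear SVM — and
#' returns the held-out metrics. Fully reproducible given `run_seed`.
#'
#' @param table labeled [sample_table].
#' @param config an [ecp_config()].
#' @param run_seed integer seed for this run's split and training.
#' @return a `metrics_report` with the fitted stage models attached as
#'   `attr(, "models")`.
#' @export
ecp_run_once <- function(table, config = ecp_config(),
                         run_seed = derive_seed(config$seed, 1L)) {
  stopifnot(inherits(table, "sample_table"))
  if (is.null(table$y)) config_error("table is unlabeled; pipeline evaluation needs labels")
  if (config$strict_no_leakage) {
    sp <- stratified_split(table$y, config$test_fraction, seed = run_seed)
    prep <- prepare_strict(table, config, sp)
    res <- run_split(prep, table$y, config, run_seed)
    nmf_model <- prep$nmf
  } else {
    prep <- prepare_full(table, config)
    res <- run_split(prep$latent, table$y, config, run_seed)
    nmf_model <- prep$nmf
  }
  out <- res$metrics
  attr(out, "models") <- list(nmf = nmf_model, dbn = res$dbn, svm = res$svm,
                              split = res$split)
  out
}

#' Repeated-split evaluation of the pipeline
#'
#' Runs `config$n_runs` independent stratified splits (per-run seeds are
#' `seed + 1 .. seed + n_runs`) and aggregates the five measures. Under
#' the default protocol the factorization is computed once on the full
#' matrix and shared across runs; everything downstream (belief network,
#' SVM) is retrained per split. In strict mode the factorization too is
#' refitted per split on training rows only.
#'
#' @param table labeled [sample_table].
#' @param config an [ecp_config()].
#' @return object of class `ecp_result`: list with `per_run` (list of
#'   `metrics_report`), `runs` (data.frame, one row per run),
#'   `summary` (mean and sd per measure), `run_seeds` and the echoed
#'   `config`.
#' @export
ecp_run_repeated <- function(table, config = ecp_config()) {
  stopifnot(inherits(table, "sample_table"))
  if (is.null(table$y)) config_error("table is unlabeled; pipeline evaluation needs labels")
  run_seeds <- vapply(seq_len(config$n_runs), function(r) derive_seed(config$seed, r),
                      integer(1L))
  if (!config$strict_no_leakage) prep <- prepare_full(table, config)
  per_run <- lapply(run_seeds, function(rs) {
    if (config$strict_no_leakage) {
      sp <- stratified_split(table$y, config$test_fraction, seed = rs)
      run_split(prepare_strict(table, config, sp), table$y, config, rs)$metrics
    } else {
      run_split(prep$latent, table$y, config, rs)$metrics
    }
  })
  runs <- do.call(rbind, lapply(per_run, metrics_row))
  runs <- cbind(run = seq_len(config$n_runs), run_seed = run_seeds, runs)
  summ <- data.frame(metric = metric_names,
                     mean = vapply(metric_names, function(m) mean(runs[[m]]), numeric(1L)),
                     sd = vapply(metric_names, function(m) stats::sd(runs[[m]]), numeric(1L)))
  rownames(summ) <- NULL
  structure(list(per_run = per_run, runs = runs, summary = summ,
                 run_seeds = run_seeds, config = config),
            class = "ecp_result")
}

#' @export
print.ecp_result <- function(x, ...) {
  cat(sprintf("<ecp_result> %d runs (k = %d, test fraction %.2f)\n",
              x$config$n_runs, x$config$k, x$config$test_fraction))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f (sd %.4f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
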