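#' Synthetic clinical-table configuration
#'
#' Describes the generator standing in for the private hospital cohort.
#' Defaults state the emulated world once: 270 patients, 50 mixed
#' features in three blocks (10 binary demographic/behavioral indicators,
#' 25 endoscopic measurements, 15 blood-test values), a planted
#' nonnegative rank-5 latent structure that both generates the features
#' and drives the labels, 10 pure-noise (redundant) columns, and a 10%
#' early-cancer prevalence — a strong minority class, as in screening
#' cohorts.
#'
#' @param n number of patients (default 270).
#' @param m number of features (default 50).
#' @param k_true planted latent rank (default 5).
#' @param positive_rate target label prevalence in `(0, 1)` (default
#'   0.10); the logistic intercept is calibrated so the realized
#'   prevalence lands within two percentage points of it.
#' @param noise_sd sd of the additive Gaussian feature noise (default
#'   0.5; the planted signal entries have mean `k_true / 2` and sd about
#'   1.2, so this is moderate measurement noise).
#' @param n_noise_features number of label-irrelevant columns regenerated
#'   as pure noise (default 10; the last columns).
#' @param feature_blocks integer vector of the three block sizes
#'   (binary, endoscopic, blood); must sum to `m`. Binary-block columns
#'   are thresholded at their median.
#' @param label_sharpness slope of the logistic label model on the latent
#'   scores (default 4). `Inf` makes labels a deterministic threshold of
#'   the score — a separable-by-construction world.
#' @param margin_gap only with `label_sharpness = Inf`: latent rows whose
#'   score falls within `margin_gap` score-sd of the threshold are
#'   redrawn, planting a clear class margin (default 0 = off).
#' @param seed integer.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 270L, m = 50L, k_true = 5L,
                             positive_rate = 0.10, noise_sd = 0.5,
                             n_noise_features = 10L,
                             feature_blocks = c(10L, 25L, 15L),
                             label_sharpness = 4, margin_gap = 0,
                             seed = 1L) {
  cfg <- list(n = as.integer(n), m = as.integer(m), k_true = as.integer(k_true),
              positive_rate = positive_rate, noise_sd = noise_sd,
              n_noise_features = as.integer(n_noise_features),
              feature_blocks = as.integer(feature_blocks),
              label_sharpness = label_sharpness, margin_gap = margin_gap,
              seed = as.integer(seed))
  if (cfg$n < 4L || cfg$m < 1L) config_error("need n >= 4 and m >= 1")
  if (sum(cfg$feature_blocks) != cfg$m) {
    config_error("feature_blocks sum to %d, must equal m = %d", sum(cfg$feature_blocks), cfg$m)
  }
  if (cfg$k_true < 1L || cfg$k_true > min(cfg$n, cfg$m)) {
    config_error("k_true = %d out of [1, %d]", cfg$k_true, min(cfg$n, cfg$m))
  }
  if (cfg$positive_rate <= 0 || cfg$positive_rate >= 1) config_error("positive_rate must be in (0, 1)")
  if (round(cfg$n * cfg$positive_rate) < 2L || round(cfg$n * (1 - cfg$positive_rate)) < 2L) {
    config_error("positive_rate %.3f unreachable with n = %d (each class needs >= 2)",
                 cfg$positive_rate, cfg$n)
  }
  if (cfg$noise_sd < 0) config_error("noise_sd must be >= 0")
  if (cfg$n_noise_features < 0L || cfg$n_noise_features > cfg$m) {
    config_error("n_noise_features out of [0, m]")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic clinical table
#'
#' Builds `X = clip0(U V + eps)` with entrywise-nonnegative gamma factors
#' `U` (`n x k_true`, shape 2, rate 2) and `V` (`k_true x m`), centered
#' Gaussian noise of sd `noise_sd`, then (i) regenerates the last
#' `n_noise_features` columns as pure gamma noise matched to the signal's
#' mean (the redundant attributes), (ii) thresholds the binary block at
#' each column's median, and (iii) draws labels from a logistic model on
#' the first two latent factors, with the intercept calibrated so the
#' realized prevalence is within two percentage points of
#' `positive_rate` (if the Bernoulli draw falls outside that band, the
#' samples with the most extreme class probabilities are flipped to the
#' nearest in-band count — deterministic, seeded). All label signal lives
#' in `U`; the noise columns carry none.
#'
#' @param config a [synthetic_config()].
#' @return a labeled [sample_table], with the generating `U`, `V`, score
#'   vector and config attached as `attr(, "truth")`.
#' @export
generate_samples <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n; m <- config$m; k <- config$k_true
  with_seed(config$seed, {
    U <- matrix(stats::rgamma(n * k, shape = 2, rate = 2), n, k)
    beta <- c(rep(1, min(2L, k)), rep(0, max(0L, k - 2L)))

    score <- as.vector(U %*% beta)
    if (is.infinite(config$label_sharpness) && config$margin_gap > 0) {
      # Re-draw rows that fall inside the forbidden band around the
      # threshold so the two classes have a real margin in latent space.
      for (pass in 1:200) {
        thr <- stats::quantile(score, 1 - config$positive_rate, names = FALSE, type = 1)
        gap <- config$margin_gap * stats::sd(score)
        inside <- which(abs(score - thr) < gap & score != thr)
        if (!length(inside)) break
        U[inside, ] <- matrix(stats::rgamma(length(inside) * k, 2, 2), length(inside), k)
        score <- as.vector(U %*% beta)
      }
    }

    V <- matrix(stats::rgamma(k * m, shape = 2, rate = 2), k, m)
    S <- U %*% V
    X <- S + if (config$noise_sd > 0) {
      matrix(stats::rnorm(n * m, sd = config$noise_sd), n, m)
    } else 0
    X <- pmax(X, 0)

    if (config$n_noise_features > 0L) {
      noise_cols <- seq.int(m - config$n_noise_features + 1L, m)
      target_mean <- mean(S)
      X[, noise_cols] <- matrix(stats::rgamma(n * length(noise_cols), shape = 2,
                                              rate = 2 / target_mean),
                                n, length(noise_cols))
    }

    n_bin <- config$feature_blocks[1L]
    if (n_bin > 0L) {
      for (j in seq_len(n_bin)) X[, j] <- as.numeric(X[, j] > stats::median(X[, j]))
    }

    if (is.infinite(config$label_sharpness)) {
      thr <- stats::quantile(score, 1 - config$positive_rate, names = FALSE, type = 1)
      y <- as.numeric(score > thr)
    } else {
      s <- config$label_sharpness
      target <- config$positive_rate
      f <- function(t) mean(sigmoid(s * (score - t))) - target
      thr <- stats::uniroot(f, lower = min(score) - 50, upper = max(score) + 50)$root
      p <- sigmoid(s * (score - thr))
      y <- stats::rbinom(n, 1L, p)
      # Calibration band: realized prevalence must sit within +/- 2
      # percentage points of the target; flip the most extreme
      # probabilities toward the nearest in-band count if not.
      lo <- ceiling((target - 0.02) * n); hi <- floor((target + 0.02) * n)
      lo <- max(lo, 2L); hi <- min(hi, n - 2L)
      pos <- sum(y)
      if (pos < lo) {
        cand <- order(-p, seq_len(n))
        cand <- cand[y[cand] == 0]
        y[cand[seq_len(lo - pos)]] <- 1
      } else if (pos > hi) {
        cand <- order(p, seq_len(n))
        cand <- cand[y[cand] == 1]
        y[cand[seq_len(pos - hi)]] <- 0
      }
    }

    block_names <- c(sprintf("demo_%02d", seq_len(config$feature_blocks[1L])),
                     sprintf("endo_%02d", seq_len(config$feature_blocks[2L])),
                     sprintf("blood_%02d", seq_len(config$feature_blocks[3L])))
    tab <- sample_table(X, sample_ids = sprintf("P%04d", seq_len(n)),
                        feature_names = block_names, y = y)
    attr(tab, "truth") <- list(U = U, V = V, score = score, config = config)
    tab
  })
}

#' Canonical seeded reference fixture
#'
#' The fixture used across the test suite and documentation (seed
#' 20191122, fixed for reproducibility across releases). Three variants of
#' the same world:
#' * `"default"` — the stated defaults of [synthetic_config()];
#' * `"noiseless"` — `noise_sd = 0`, all-continuous columns, no redundant
#'   columns: `X` has numerical rank exactly `k_true`, so factorization
#'   at the planted rank reconstructs it almost exactly;
#' * `"separable"` — noiseless plus deterministic threshold labels with a
#'   planted margin (`label_sharpness = Inf`, `margin_gap = 0.5`): the
#'   classes are separable by construction in latent space.
#'
#' @param variant one of `"default"`, `"noiseless"`, `"separable"`.
#' @param seed fixture seed (default 20191122).
#' @return a labeled [sample_table].
#' @export
make_reference_fixture <- function(variant = c("default", "noiseless", "separable"),
                                   seed = 20191122L) {
  variant <- match.arg(variant)
  cfg <- switch(variant,
    default = synthetic_config(seed = seed),
    noiseless = synthetic_config(noise_sd = 0, feature_blocks = c(0L, 35L, 15L),
                                 n_noise_features = 0L, seed = seed),
    separable = synthetic_config(noise_sd = 0, feature_blocks = c(0L, 35L, 15L),
                                 n_noise_features = 0L, label_sharpness = Inf,
                                 margin_gap = 0.5, seed = seed))
  generate_samples(cfg)
}
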