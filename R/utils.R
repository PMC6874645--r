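# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library functions never perturb
# user-level randomness. All exported functions taking a `seed` argument
# funnel through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive the per-run seed from a master seed and a run counter, kept within
# the 32-bit integer range R requires.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) + as.double(counter)) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Configuration/validation failures get their own condition class so the
# command-line layer can map them to exit status 2.
config_error <- function(fmt, ...) {
  stop(structure(
    class = c("ecp_config_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

is_binary01 <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x == 0 | x == 1)
}

# Min-max rescale the columns of a matrix to [0, 1] using the supplied
# per-column minima and ranges; degenerate (zero-range) columns map to 0.
minmax_apply <- function(X, mins, ranges, clip = FALSE) {
  out <- sweep(X, 2L, mins, "-")
  safe <- ifelse(ranges > 0, ranges, 1)
  out <- sweep(out, 2L, safe, "/")
  out[, ranges <= 0] <- 0
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}
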