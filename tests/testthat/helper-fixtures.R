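# Shared fixtures, all generated in code. Expensive simulated sessions are
# memoized per test run so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# A small but complete participant configuration: full band structure at a
# quarter of the default data volume (16 channels, 96 trials).
small_config <- function(seed = 101, ...) {
  sim_config(n_channels = 16L, n_trials = 96L, seed = seed, ...)
}

small_participant <- function() {
  memo("small_participant", simulate_participant(small_config(), participant = 1L))
}

small_epochs <- function() {
  memo("small_epochs", {
    p <- small_participant()
    preprocess_session(p$task, p$resting, ica_seed = 5L)
  })
}

small_fit <- function() {
  memo("small_fit", fit_participant(small_epochs(), id = 1L))
}

# Single planted source with strong comodulation in an otherwise quiet
# recording: the parameter-recovery setting (32 channels).
recovery_config <- function(seed = 202, alpha = 0.8) {
  sim_config(
    seed = seed,
    source_specs = list(source_spec(10, 4, baseline_log_variance = log(400),
                                    comodulation = alpha)),
    n_background = 4L, background_sd = 5, noise_sd = 2
  )
}

# Deterministic random ridge problem.
ridge_problem <- function(n = 20, p = 10, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, sd = 0.5)
  list(X = X, y = y)
}

expect_abs_cos_gt <- function(a, b, threshold) {
  cs <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cs, threshold)
}
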