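# SPoC: covariance construction, the generalized eigenproblem, forward-model
# patterns and log-variance features. Oracles live in helper-oracles.R.

test_that("per-epoch covariances follow the stated estimator", {
  # single channel: per-epoch covariance equals the sample variance
  set.seed(1)
  arr <- array(rnorm(2 * 1 * 500), c(2, 1, 500))
  cs <- epoch_covariances(arr, c(-1, 1))
  expect_equal(drop(cs$per_epoch[[1]]), var(arr[1, 1, ]))
  expect_equal(drop(cs$per_epoch[[2]]), var(arr[2, 1, ]))

  # duplicated channels: rank 1
  arr2 <- array(0, c(2, 2, 100))
  y <- rnorm(100)
  arr2[1, 1, ] <- y; arr2[1, 2, ] <- y
  y2 <- rnorm(100)
  arr2[2, 1, ] <- y2; arr2[2, 2, ] <- y2
  cs2 <- epoch_covariances(arr2, c(-1, 1))
  expect_lt(abs(det(cs2$per_epoch[[1]])), 1e-12)

  # white noise: off-diagonals of the grand mean shrink
  set.seed(2)
  E <- 60
  arr3 <- array(rnorm(E * 4 * 250), c(E, 4, 250))
  cs3 <- epoch_covariances(arr3, rnorm(E))
  off <- cs3$C[upper.tri(cs3$C)]
  expect_lt(max(abs(off)) / mean(diag(cs3$C)), 0.1)

  expect_error(epoch_covariances(array(NA_real_, c(2, 2, 10)), c(0, 1)),
               "non-finite")
})

test_that("the eigensolution matches brute-force covariance maximization", {
  sim <- sim_epochs_2ch(seed = 3)
  cs <- epoch_covariances(sim$arr, sim$z)
  fit <- fit_spoc(cs)
  bf <- brute_force_spoc_2ch(cs$per_epoch, cs$C, cs$z)
  expect_abs_cos_gt(fit$w, bf$w, 0.99)
  # channel 1 carries the comodulation
  expect_abs_cos_gt(fit$w, c(1, 0), 0.99)

  # the eigenvalue equals the empirical covariance of power with z
  p <- vapply(cs$per_epoch, function(Ce) drop(t(fit$w) %*% Ce %*% fit$w), 0)
  expect_equal(mean(p * cs$z), fit$eigenvalue, tolerance = 1e-8)
})

test_that("optimality: the filter beats 10000 random unit-C-norm filters", {
  set.seed(4)
  E <- 80
  arr <- array(rnorm(E * 4 * 150), c(E, 4, 150))
  z <- rnorm(E)
  # plant mild structure on a random direction
  d <- spocridge:::unit_norm(rnorm(4))
  for (e in seq_len(E)) {
    arr[e, , ] <- arr[e, , ] + d %*% t(rnorm(150, sd = sqrt(exp(0.4 * z[e]))))
  }
  cs <- epoch_covariances(arr, z)
  fit <- fit_spoc(cs)
  obj <- function(w) {
    w <- w / sqrt(drop(t(w) %*% cs$C %*% w))
    p <- vapply(cs$per_epoch, function(Ce) drop(t(w) %*% Ce %*% w), 0)
    abs(mean(p * cs$z))
  }
  best_random <- max(vapply(seq_len(10000), function(i) obj(rnorm(4)), 0))
  expect_gte(abs(fit$eigenvalue) + 1e-12, best_random)
})

test_that("a label with no power comodulation yields a null eigenvalue", {
  set.seed(5)
  E <- 150
  arr <- array(rnorm(E * 3 * 200), c(E, 3, 200))
  z <- rnorm(E)
  cs <- epoch_covariances(arr, z)
  fit <- fit_spoc(cs)
  # permutation null for the largest |eigenvalue|
  null_vals <- vapply(seq_len(200), function(i) {
    csp <- cs
    csp$z <- sample(cs$z)
    csp$Cz <- Reduce(`+`, Map(`*`, cs$per_epoch, csp$z)) / E
    abs(fit_spoc(csp)$eigenvalue)
  }, 0)
  expect_lt(abs(fit$eigenvalue), quantile(null_vals, 0.99))
})

test_that("negating the label negates the eigenvalue but keeps the filter", {
  sim <- sim_epochs_2ch(seed = 6)
  cs_pos <- epoch_covariances(sim$arr, sim$z)
  cs_neg <- epoch_covariances(sim$arr, -sim$z)
  f_pos <- fit_spoc(cs_pos)
  f_neg <- fit_spoc(cs_neg)
  expect_equal(f_neg$eigenvalue, -f_pos$eigenvalue, tolerance = 1e-9)
  expect_abs_cos_gt(f_pos$w, f_neg$w, 1 - 1e-9)
})

test_that("forward-model patterns are scale-invariant and recover topographies", {
  # C = identity: pattern proportional to w
  w <- c(0.6, 0.8)
  expect_abs_cos_gt(compute_pattern(w, diag(2)), w, 1 - 1e-12)
  # rescaling w leaves the pattern unchanged
  C <- crossprod(matrix(rnorm(9), 3))
  w3 <- rnorm(3)
  expect_equal(compute_pattern(w3, C), compute_pattern(7 * w3, C))

  # planted 32-channel source: pattern matches the planted topography
  p <- memo("recovery_participant",
            simulate_participant(recovery_config(), participant = 1L))
  ep <- memo("recovery_epochs",
             preprocess_session(p$task, p$resting, ica_seed = 6L))
  pf <- memo("recovery_fit", fit_participant(ep, id = 1L))
  topo <- p$task$ground_truth$sources[[1]]$topography
  pat <- pf$filters$filters[[3]]$pattern   # 10 Hz band
  expect_abs_cos_gt(pat, topo, 0.95)
})

test_that("log-variance features behave as band-power estimates", {
  # identity projection of a unit-variance signal: feature near 0
  set.seed(7)
  E <- 40
  arr <- array(rnorm(E * 1 * 500), c(E, 1, 500))
  es <- structure(list(
    data = list(arr), meta = data.frame(i = seq_len(E)),
    bands = list(list(center = 10)), sampling_rate = 1000,
    channel_labels = "Cz", cropped = TRUE), class = "epoch_set")
  fs <- structure(list(
    filters = list(list(w = 1)), bands = list(list(center = 10)),
    channel_labels = "Cz"), class = "spatial_filter_set")
  X <- extract_features(es, fs)
  expect_lt(abs(mean(X)), 0.05)

  # doubling the amplitude adds log 4
  es2 <- es
  es2$data[[1]] <- arr * 2
  X2 <- extract_features(es2, fs)
  expect_equal(unname(X2 - X), matrix(log(4), E, 1), tolerance = 1e-12)

  # planted comodulation shows up in the planted band's feature
  pf <- small_fit()
  expect_gt(abs(cor(pf$train$features[, 3], pf$train$z)), 0.2)

  expect_error(extract_features(es, structure(list(
    filters = list(list(w = 1), list(w = 1)),
    bands = list(list(center = 1), list(center = 2)),
    channel_labels = "Cz"), class = "spatial_filter_set")),
    "band count mismatch")
})

test_that("hold-out features change only through their own epochs (no leakage)", {
  pf <- small_fit()
  es <- small_epochs()
  sp <- split_epochs(es)
  # perturb the training epochs heavily; hold-out features stay identical
  # when extracted with frozen filters
  X_hold_1 <- extract_features(sp$holdout, pf$filters)
  sp$train$data <- lapply(sp$train$data, function(a) a * 3 + 1)
  X_hold_2 <- extract_features(sp$holdout, pf$filters)
  expect_identical(X_hold_1, X_hold_2)
})
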