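# ICA, filter bank, epoching and retention rules.

make_session <- function(signal, fs = 1000, labels = montage_labels(nrow(signal)),
                         trials = NULL, events = NULL, gt = NULL) {
  structure(list(signal = signal, sampling_rate = fs, channel_labels = labels,
                 events = events, trials = trials, ground_truth = gt),
            class = "raw_session")
}

test_that("ICA recovers planted mixing directions up to permutation and sign", {
  set.seed(1)
  n <- 20000
  # two super-Gaussian sources mixed into 4 channels
  s1 <- rnorm(n)^3
  s2 <- runif(n, -2, 2)
  A <- cbind(c(1, 0.5, 0.2, 0), c(0, 0.3, 1, 0.8))
  x <- A %*% rbind(s1, s2) + matrix(rnorm(4 * n, sd = 0.01), 4)
  sess <- make_session(x)
  ica <- fit_ica(sess, seed = 2)
  match_cos <- function(target) {
    max(apply(ica$mixing, 2, function(m) {
      abs(sum(m * target)) / sqrt(sum(m^2) * sum(target^2))
    }))
  }
  expect_gt(match_cos(A[, 1]), 0.95)
  expect_gt(match_cos(A[, 2]), 0.95)

  # determinism
  ica2 <- fit_ica(sess, seed = 2)
  expect_identical(ica$unmixing, ica2$unmixing)

  # identity mixing of independent non-Gaussian channels: unmixing is a
  # scaled permutation of identity
  y <- rbind(rnorm(n)^3, runif(n, -1, 1), rnorm(n)^3 + runif(n, -3, 3))
  ica3 <- fit_ica(make_session(y), seed = 3)
  P <- abs(ica3$unmixing %*% diag(apply(y, 1, sd)))
  P <- P / apply(P, 1, max)
  expect_true(all(rowSums(P > 0.9) == 1))
  expect_true(all(colSums(P > 0.9) == 1))

  # rank-deficient input names dependent channels
  z <- rbind(rnorm(n), rnorm(n))
  z <- rbind(z, z[1, ] + z[2, ])
  expect_error(fit_ica(make_session(z)), "rank-deficient")
})

test_that("artifact component selection is config-first with blink heuristic fallback", {
  cfg <- small_config(seed = 41)
  rest <- generate_resting_state(cfg)
  ica <- fit_ica(rest, seed = 4)
  expect_identical(select_artifact_components(ica, rest, reject = c(1L, 4L)),
                   c(1L, 4L))
  auto <- select_artifact_components(ica, rest)
  expect_equal(length(auto), 1)
  bt <- rest$ground_truth$blink_topography
  expect_abs_cos_gt(ica$mixing[, auto], bt, 0.95)

  cfg0 <- small_config(seed = 41)
  cfg0$artifact$rate_per_min <- 0
  rest0 <- generate_resting_state(cfg0)
  ica0 <- fit_ica(rest0, seed = 4)
  expect_equal(length(select_artifact_components(ica0, rest0)), 0)
})

test_that("ICA cleaning removes rejected components and nothing else", {
  p <- small_participant()
  ica <- fit_ica(p$resting, seed = 5)
  # empty rejection: reconstruction is the identity
  clean0 <- apply_ica_cleaning(p$task, ica, integer(0))
  rel <- max(abs(clean0$signal - p$task$signal)) / max(abs(p$task$signal))
  expect_lt(rel, 1e-6)

  # rejecting the blink component suppresses the blink time course but keeps
  # the planted oscillatory source
  rej <- select_artifact_components(ica, p$resting)
  expect_gte(length(rej), 1)
  clean <- apply_ica_cleaning(p$task, ica, rej)
  gt <- p$task$ground_truth
  blink_tc <- numeric(ncol(p$task$signal))
  for (t0 in gt$blink_times) {
    blink_tc[(t0 + 1):(t0 + 300)] <- sin(pi * seq(0, 1, length.out = 300))^2
  }
  frontal <- which(p$task$channel_labels == "Fp1")
  expect_gt(abs(cor(p$task$signal[frontal, ], blink_tc)), 0.4)
  expect_lt(abs(cor(clean$signal[frontal, ], blink_tc)), 0.1)
  # outside the blink windows (where the raw projection is itself blink-free)
  # the planted-source projection is preserved
  mask <- rep(TRUE, ncol(p$task$signal))
  for (t0 in gt$blink_times) mask[(t0 + 1):(t0 + 300)] <- FALSE
  topo <- gt$sources[[1]]$topography
  expect_gt(cor(drop(topo %*% p$task$signal)[mask],
                drop(topo %*% clean$signal)[mask]), 0.9)

  # rejecting everything zeroes the signal
  all_rej <- seq_len(nrow(ica$unmixing))
  cleanall <- apply_ica_cleaning(p$task, ica, all_rej)
  expect_lt(max(abs(cleanall$signal)), 1e-8)

  expect_error(apply_ica_cleaning(make_session(matrix(rnorm(100), 2)), ica),
               "channel count mismatch")
})

test_that("filter bank satisfies the passband and stopband contracts", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  bands <- band_definitions(sampling_rate = fs)
  sine10 <- sin(2 * pi * 10 * t)
  sess <- make_session(rbind(sine10, 0 * t), fs = fs, labels = c("A", "B"))
  out <- apply_filter_bank(sess, bands)

  mid <- 1000:3000  # avoid edges
  # 10 Hz through the 10 Hz band (index 3): unit gain, zero lag
  y <- out[[3]]$signal[1, ]
  expect_lt(abs(sd(y[mid]) / sd(sine10[mid]) - 1), 0.05)
  cc <- ccf(y[mid], sine10[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # 10 Hz through the 22 Hz band (index 6): attenuated at least 20 dB
  y22 <- out[[6]]$signal[1, ]
  expect_lt(sd(y22[mid]) / sd(sine10[mid]), 0.1)

  # zero in, zero out
  expect_lt(max(abs(out[[5]]$signal[2, ])), 1e-12)

  # above-Nyquist band errors
  expect_error(apply_filter_bank(sess, band_definitions(centers = 600,
                                                        sampling_rate = fs)),
               "Nyquist")
})

test_that("marker-based epoching yields one epoch per presentation phase", {
  p <- small_participant()
  es <- epoch_session(p$task)
  expect_equal(nrow(es$meta), 2 * nrow(p$trials))
  expect_equal(sum(es$meta$phase == "fixation"), nrow(p$trials))
  expect_equal(sum(es$meta$phase == "stimulus"), nrow(p$trials))

  # stimulus epoch content equals the raw slice [onset, end)
  i <- which(es$meta$phase == "stimulus")[1]
  tr1 <- p$trials[p$trials$trial_index == es$meta$trial_index[i], ]
  expect_identical(es$data[[1]][[i]],
                   p$task$signal[, (tr1$stimulus_onset + 1):tr1$stimulus_end,
                                 drop = FALSE])

  # truncated session: 1 trial gives 2 epochs
  one <- p$task
  one$trials <- p$trials[1, ]
  one$events <- p$task$events[p$task$events$trial_index == 1, ]
  expect_equal(nrow(epoch_session(one)$meta), 2)

  # orphan markers are reported with the trial index
  bad <- p$task
  bad$events <- bad$events[-which(bad$events$marker == "stimulus_on")[3], ]
  expect_error(epoch_session(bad), "markers for trial")
})

test_that("retention rules drop fixation, incorrect and too-early epochs and crop to 500 ms", {
  cfg <- sim_config(n_channels = 2L, n_trials = 16L, pool_size = 32L,
                    n_background = 1L, seed = 51,
                    artifact = list(rate_per_min = 0, amplitude = 0,
                                    duration_ms = 300, in_task = FALSE))
  tr <- simulate_behaviour(generate_schedule(cfg), cfg)
  # force a boundary layout: RT 699 (drop), RT 700 (keep), one incorrect,
  # one timeout
  tr$reaction_time_ms[1] <- 699L
  tr$reaction_time_ms[2] <- 700L
  tr$correct[1:2] <- TRUE
  tr$correct[3] <- FALSE
  tr$timeout[4] <- TRUE
  tr$correct[4] <- FALSE
  tr$reaction_time_ms[-(1:4)] <- pmax(tr$reaction_time_ms[-(1:4)], 701L)
  tr$correct[-(1:4)] <- TRUE
  tr$timeout[-(1:4)] <- FALSE
  # re-layout onsets after editing RTs
  stim_len <- tr$reaction_time_ms
  cursor <- 1000L
  for (i in seq_len(nrow(tr))) {
    tr$fixation_onset[i] <- cursor
    tr$stimulus_onset[i] <- cursor + tr$fixation_duration_ms[i]
    cursor <- tr$stimulus_onset[i] + stim_len[i]
  }
  tr$stimulus_end <- tr$stimulus_onset + stim_len
  tr$response_sample <- ifelse(tr$timeout, NA_integer_, tr$stimulus_end)
  sess <- synthesize_eeg(tr, cfg)

  bands <- band_definitions()[c(3, 6)]
  es <- epoch_session(apply_filter_bank(sess, bands))
  kept <- filter_and_crop_epochs(es)

  expect_equal(nrow(kept$meta), 16 - 3)
  expect_false(1 %in% kept$meta$trial_index)  # RT 699 dropped
  expect_true(2 %in% kept$meta$trial_index)   # RT 700 retained
  expect_false(any(c(3, 4) %in% kept$meta$trial_index))
  expect_true(all(kept$meta$phase == "stimulus"))
  expect_equal(dim(kept$data[[1]]), c(13, 2, 500))
  expect_equal(unname(kept$removal_counts["fixation"]), 16)
  expect_equal(unname(kept$removal_counts["incorrect_or_missing"]), 2)
  expect_equal(unname(kept$removal_counts["too_early"]), 1)

  # retained window never overlaps the final 200 ms before the response
  rts <- kept$meta$reaction_time_ms
  expect_true(all(500 <= rts - 200))

  # retention is order-independent: same set via any predicate order
  m <- es$meta
  drop_a <- m$phase == "fixation"
  drop_b <- !m$correct | m$timeout
  drop_c <- m$reaction_time_ms < 700
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    rules <- list(drop_a, drop_b, drop_c)[perm]
    keep <- !(rules[[1]] | rules[[2]] | rules[[3]])
    keep[m$phase == "fixation"] <- FALSE
    expect_equal(m$trial_index[keep & m$phase == "stimulus"],
                 kept$meta$trial_index)
  }
})

test_that("fast filter-and-epoch path equals the full filter-bank path", {
  cfg <- sim_config(n_channels = 3L, n_trials = 8L, pool_size = 16L,
                    n_background = 1L, seed = 61)
  tr <- simulate_behaviour(generate_schedule(cfg), cfg)
  sess <- synthesize_eeg(tr, cfg)
  bands <- band_definitions()[c(1, 3, 8)]

  slow <- filter_and_crop_epochs(epoch_session(apply_filter_bank(sess, bands)))
  fast <- spocridge:::band_epoch_arrays(sess$signal, slow$meta$start, bands)
  for (b in seq_along(bands)) {
    expect_equal(fast[[b]], slow$data[[b]], tolerance = 1e-9)
  }
})

test_that("epoch containers round-trip through the on-disk format", {
  es <- small_epochs()
  path <- withr::local_tempfile(fileext = ".rds")
  write_epochs(es, path)
  back <- read_epochs(path)
  expect_equal(back$meta, es$meta)
  expect_equal(back$data[[3]], es$data[[3]])
  expect_error(read_epochs("does-not-exist.rds"), "missing")
})
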