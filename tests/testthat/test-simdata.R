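test_that("schedules are exactly stratified and seed-deterministic", {
  cfg <- sim_config(seed = 3)
  sch <- generate_schedule(cfg)
  expect_equal(nrow(sch), 192)
  cells <- table(sch$angle, sch$mirrored)
  expect_true(all(cells == 24))
  expect_true(all(!duplicated(sch$pool_id)))
  expect_true(all(sch$pool_id >= 1 & sch$pool_id <= 384))
  expect_true(all(sch$fixation_duration_ms >= 1000 & sch$fixation_duration_ms <= 3000))
  expect_identical(sch, generate_schedule(cfg))

  cfg2 <- sim_config(angles = 0, accuracy_by_angle = 0.9, n_trials = 2,
                     pool_size = 4, seed = 1)
  sch2 <- generate_schedule(cfg2)
  expect_equal(nrow(sch2), 2)
  expect_true(all(sch2$angle == 0))

  expect_error(sim_config(n_trials = 190), "divisible")
})

test_that("behaviour follows the truncated log-normal reaction-time model", {
  cfg0 <- sim_config(rt_model = list(baseline_log_ms = log(1500),
                                     slope_per_degree = 0, sd_log = 0),
                     accuracy_by_angle = rep(1, 4), seed = 5)
  tr0 <- simulate_behaviour(generate_schedule(cfg0), cfg0)
  expect_true(all(tr0$reaction_time_ms == 1500))
  expect_true(all(tr0$correct))
  expect_true(all(diff(tr0$fixation_onset) > 0))
  expect_equal(tr0$response_sample - tr0$stimulus_onset, tr0$reaction_time_ms)

  # Monte-Carlo check of the generative line at large n (population of draws
  # unaffected by truncation for these parameters)
  cfgN <- sim_config(n_trials = 9600L, pool_size = 9600L, seed = 6)
  trN <- simulate_behaviour(generate_schedule(cfgN), cfgN)
  for (a in cfgN$angles) {
    x <- log(trN$reaction_time_ms[trN$angle == a])
    mu <- cfgN$rt_model$baseline_log_ms + cfgN$rt_model$slope_per_degree * a
    se <- cfgN$rt_model$sd_log / sqrt(length(x))
    expect_lt(abs(mean(x) - mu), 3 * se)
  }
  means <- tapply(log(trN$reaction_time_ms), trN$angle, mean)
  expect_true(all(diff(means) > 0))
})

test_that("planted sources carry the configured power-label comodulation", {
  p <- small_participant()
  gt <- p$task$ground_truth
  z <- gt$z
  # realized epoch variances of the planted alpha source track exp(alpha * z)
  for (k in seq_along(gt$sources)) {
    src <- gt$sources[[k]]
    expect_equal(src$realized_variance, src$target_variance, tolerance = 1e-10)
    if (src$comodulation == 0) {
      # exact rescaling: variance constant across epochs, no comodulation
      expect_lt(max(abs(src$realized_variance / src$realized_variance[1] - 1)),
                1e-10)
    } else {
      r <- cor(log(src$realized_variance), z)
      expect_gt(r * sign(src$comodulation), 0.6)
    }
  }
  # comodulation measurable in the mixed signal grows monotonically with
  # |alpha|: project the session through the planted topography and correlate
  # epoch log-variance with z (background sources blur the relation)
  cors <- vapply(c(0, 0.2, 0.5, 0.8), function(a) {
    cfg <- sim_config(n_channels = 8L, n_trials = 96L, seed = 77,
                      source_specs = list(source_spec(10, 4, log(100), a)),
                      n_background = 2L)
    tr <- simulate_behaviour(generate_schedule(cfg), cfg)
    s <- synthesize_eeg(tr, cfg)
    topo <- s$ground_truth$sources[[1]]$topography
    proj <- drop(topo %*% s$signal)
    v <- vapply(tr$stimulus_onset, function(o) var(proj[(o + 1):(o + 500)]), 0)
    cor(log(v), s$ground_truth$z)
  }, 0)
  expect_true(all(diff(cors) > 0))
  expect_lt(abs(cors[1]), 0.15)
})

test_that("a single noiseless source yields a rank-1 sensor signal", {
  cfg <- sim_config(n_channels = 4L, n_trials = 8L, pool_size = 16L,
                    source_specs = list(source_spec(10, 4, log(100), 0.5)),
                    n_background = 0L, noise_sd = 0,
                    artifact = list(rate_per_min = 0, amplitude = 0,
                                    duration_ms = 300, in_task = FALSE),
                    seed = 9)
  tr <- simulate_behaviour(generate_schedule(cfg), cfg)
  s <- synthesize_eeg(tr, cfg)
  cc <- cor(t(s$signal))
  expect_true(all(abs(abs(cc) - 1) < 1e-10))
})

test_that("every trial has exactly one fixation, stimulus and response event", {
  p <- small_participant()
  ev <- p$task$events
  for (i in p$trials$trial_index) {
    sub <- ev[ev$trial_index == i, ]
    expect_equal(sum(sub$marker == "fixation_on"), 1)
    expect_equal(sum(sub$marker == "stimulus_on"), 1)
    expect_equal(sum(sub$marker %in% c("response", "timeout")), 1)
  }
  expect_false(any(!is.finite(p$task$signal)))
})

test_that("resting state has the configured duration and blink count", {
  cfg <- small_config(seed = 31)
  rest <- generate_resting_state(cfg)
  expect_equal(ncol(rest$signal), 60000)
  n_blinks <- length(rest$ground_truth$blink_times)
  # Poisson(12): essentially always within [2, 26]
  expect_gt(n_blinks, 2)
  expect_lt(n_blinks, 27)

  cfg0 <- small_config(seed = 31)
  cfg0$artifact$rate_per_min <- 0
  rest0 <- generate_resting_state(cfg0)
  expect_equal(length(rest0$ground_truth$blink_times), 0)
  env <- apply(abs(rest0$signal), 1, max)
  expect_lt(max(env) / min(env), 3)
})

test_that("seed determinism yields identical signals, different participants differ", {
  cfg <- sim_config(n_channels = 4L, n_trials = 16L, pool_size = 32L, seed = 12)
  a <- simulate_participant(cfg, participant = 1)
  b <- simulate_participant(cfg, participant = 1)
  expect_identical(a$task$signal, b$task$signal)
  expect_identical(a$trials, b$trials)
  c2 <- simulate_participant(cfg, participant = 2)
  expect_false(identical(a$task$signal, c2$task$signal))
})

test_that("session round-trips through EDF plus sidecars", {
  cfg <- sim_config(n_channels = 4L, n_trials = 8L, pool_size = 16L, seed = 21)
  p <- simulate_participant(cfg, participant = 1)
  dir <- withr::local_tempdir()
  write_session(p$task, dir, prefix = "sub-01")
  back <- read_session(dir, prefix = "sub-01")

  # 16-bit quantization bound: range / 65535 per channel
  qstep <- apply(p$task$signal, 1, function(x) diff(range(x))) / 65535
  err <- apply(abs(back$signal - p$task$signal), 1, max)
  expect_true(all(err <= qstep + 1e-12))
  expect_identical(back$channel_labels, p$task$channel_labels)
  expect_equal(back$sampling_rate, p$task$sampling_rate)
  expect_equal(back$events$sample, p$task$events$sample)
  expect_equal(back$trials$reaction_time_ms, p$trials$reaction_time_ms)
  expect_equal(back$trials$stimulus_onset, p$trials$stimulus_onset)
  expect_equal(back$trials$correct, p$trials$correct)

  # events.tsv rows: one fixation + one stimulus per trial plus one
  # response-or-timeout event per trial
  evt <- read.delim(file.path(dir, "sub-01_events.tsv"))
  expect_equal(nrow(evt), 2 * nrow(p$trials) +
                 sum(!p$trials$timeout) + sum(p$trials$timeout))

  # corrupted header fails loudly
  con <- file(file.path(dir, "sub-01_eeg.edf"), "r+b")
  writeBin(charToRaw("XXXXXXXX"), con)
  close(con)
  expect_error(read_session(dir, prefix = "sub-01"), "corrupted")
  expect_error(read_session(dir, prefix = "nope"), "missing")
})
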