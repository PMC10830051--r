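#' Configuration for a simulated mental rotation participant
#'
#' Bundles every parameter of the generator: the task schedule (trial counts,
#' angular disparities, fixation and timeout durations), the behavioural model
#' (log-normal reaction times whose mean grows linearly with angle, and an
#' angle-dependent accuracy), and the EEG source model (band-limited cortical
#' sources whose per-epoch variance comodulates with the standardized log
#' reaction time, broadband background sources, sensor noise and ocular
#' artifacts).
#'
#' @param n_channels number of EEG channels.
#' @param sampling_rate sampling rate in Hz (1 sample = 1 ms at 1 kHz).
#' @param n_trials number of trials; must be divisible by
#'   `length(angles) * 2` (mirrored/unmirrored stratification).
#' @param pool_size size of the object-pair pool sampled without replacement.
#' @param angles angular disparities in degrees.
#' @param fixation_range fixation-cross duration interval in ms.
#' @param stimulus_timeout maximal stimulus duration in ms.
#' @param rt_model list with `baseline_log_ms` (mean log RT at 0 deg),
#'   `slope_per_degree` (increase of mean log RT per degree) and `sd_log`.
#' @param accuracy_by_angle probability of a correct response per angle,
#'   monotone non-increasing in angle.
#' @param source_specs list of [source_spec()] objects; `topography = NULL`
#'   entries get a random unit-norm topography drawn from the participant's
#'   source substream.
#' @param n_background number of broadband (white) background sources.
#' @param background_sd standard deviation of each background source (uV).
#' @param noise_sd sensor-noise standard deviation per channel (uV).
#' @param artifact list with blink `rate_per_min`, `amplitude` (uV),
#'   `duration_ms`, and `in_task` (also embed blinks in task sessions).
#' @param seed integer seed; expanded into per-stage substreams.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_channels = 32L,
                       sampling_rate = 1000,
                       n_trials = 192L,
                       pool_size = 384L,
                       angles = c(0, 50, 100, 150),
                       fixation_range = c(1000, 3000),
                       stimulus_timeout = 7500,
                       rt_model = list(baseline_log_ms = log(1400),
                                       slope_per_degree = 0.004,
                                       sd_log = 0.35),
                       accuracy_by_angle = c(0.96, 0.93, 0.89, 0.84),
                       source_specs = default_source_specs(),
                       n_background = 6L,
                       background_sd = 10,
                       noise_sd = 5,
                       artifact = list(rate_per_min = 12, amplitude = 150,
                                       duration_ms = 300, in_task = TRUE),
                       seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    n_trials = as.integer(n_trials), pool_size = as.integer(pool_size),
    angles = angles, fixation_range = fixation_range,
    stimulus_timeout = stimulus_timeout, rt_model = rt_model,
    accuracy_by_angle = accuracy_by_angle, source_specs = source_specs,
    n_background = as.integer(n_background), background_sd = background_sd,
    noise_sd = noise_sd, artifact = artifact, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  n_cells <- length(cfg$angles) * 2L
  if (cfg$n_trials %% n_cells != 0) {
    stop("n_trials (", cfg$n_trials, ") must be divisible by the number of ",
         "angle x mirrored cells (", n_cells, ")")
  }
  if (cfg$pool_size %% n_cells != 0 || cfg$pool_size < cfg$n_trials) {
    stop("pool_size must be a multiple of the cell count and >= n_trials")
  }
  if (any(cfg$accuracy_by_angle <= 0) || any(cfg$accuracy_by_angle > 1)) {
    stop("accuracy_by_angle probabilities must lie in (0, 1]")
  }
  if (length(cfg$accuracy_by_angle) != length(cfg$angles)) {
    stop("accuracy_by_angle must give one probability per angle")
  }
  if (is.unsorted(rev(cfg$accuracy_by_angle))) {
    stop("accuracy_by_angle must be monotone non-increasing in angle")
  }
  if (cfg$fixation_range[1] <= 0 || cfg$fixation_range[2] > cfg$stimulus_timeout ||
      cfg$fixation_range[1] > cfg$fixation_range[2]) {
    stop("fixation_range must lie within (0, stimulus_timeout]")
  }
  nyq <- cfg$sampling_rate / 2
  for (s in cfg$source_specs) {
    if (s$band_center + s$band_width / 2 >= nyq) {
      stop("source band entirely or partly above Nyquist")
    }
    if (!is.null(s$topography)) {
      if (length(s$topography) != cfg$n_channels) {
        stop("source topography length must equal n_channels")
      }
      if (abs(sqrt(sum(s$topography^2)) - 1) > 1e-8) {
        stop("source topography must have unit Euclidean norm")
      }
    }
  }
  if (cfg$rt_model$sd_log < 0) stop("sd_log must be >= 0")
  invisible(cfg)
}

#' Specification of one planted band-limited cortical source
#'
#' The source is band-limited Gaussian noise whose variance inside each
#' stimulus epoch window equals `exp(baseline_log_variance + comodulation * z)`
#' where `z` is the trial's standardized log reaction time. A positive
#' `comodulation` plants power that grows with (relatively) slow responses; a
#' negative value emulates event-related desynchronization.
#'
#' @param band_center centre frequency in Hz.
#' @param band_width band width in Hz.
#' @param baseline_log_variance log of the source variance outside epochs (and
#'   inside epochs when `comodulation = 0`), in log-uV^2.
#' @param comodulation coefficient linking per-epoch log variance to `z`.
#' @param topography unit-norm channel-space mixing vector, or `NULL` to draw
#'   a random one at synthesis time.
#' @return a `source_spec` object.
#' @export
source_spec <- function(band_center, band_width = 4,
                        baseline_log_variance = log(400),
                        comodulation = 0, topography = NULL) {
  structure(
    list(band_center = band_center, band_width = band_width,
         baseline_log_variance = baseline_log_variance,
         comodulation = comodulation, topography = topography),
    class = "source_spec"
  )
}

#' Default planted sources: alpha-band desynchronization and a beta source
#'
#' Alpha (10 Hz) power decreases with slower responses (negative
#' comodulation, as in event-related desynchronization studies of mental
#' rotation); a weaker 22 Hz beta source comodulates positively; a 6 Hz theta
#' source carries no label information.
#'
#' @return list of [source_spec()] objects.
#' @export
default_source_specs <- function() {
  list(
    source_spec(10, 4, baseline_log_variance = log(400), comodulation = -0.8),
    source_spec(22, 4, baseline_log_variance = log(225), comodulation = 0.5),
    source_spec(6, 4, baseline_log_variance = log(225), comodulation = 0)
  )
}

#' Generate a stratified trial schedule
#'
#' Samples `n_trials` object pairs without replacement from a pool stratified
#' over angle x mirrored cells (equal pool share per cell), draws i.i.d.
#' uniform fixation durations, and shuffles the presentation order.
#' Behavioural columns are filled by [simulate_behaviour()].
#'
#' @param config a [sim_config()].
#' @return `data.frame` trial table with columns `trial_index`, `pool_id`,
#'   `angle`, `mirrored`, `fixation_duration_ms`.
#' @export
generate_schedule <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "schedule"))
  cells <- expand.grid(angle = config$angles, mirrored = c(FALSE, TRUE))
  n_cells <- nrow(cells)
  per_cell <- config$n_trials %/% n_cells
  pool_per_cell <- config$pool_size %/% n_cells
  rows <- lapply(seq_len(n_cells), function(i) {
    pool_ids <- (i - 1L) * pool_per_cell + seq_len(pool_per_cell)
    data.frame(
      pool_id = sample(pool_ids, per_cell),
      angle = cells$angle[i],
      mirrored = cells$mirrored[i]
    )
  })
  tab <- do.call(rbind, rows)
  tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  tab$trial_index <- seq_len(nrow(tab))
  tab$fixation_duration_ms <- as.integer(round(runif(
    nrow(tab), config$fixation_range[1], config$fixation_range[2]
  )))
  rownames(tab) <- NULL
  tab[, c("trial_index", "pool_id", "angle", "mirrored", "fixation_duration_ms")]
}

#' Simulate behavioural responses for a schedule
#'
#' Reaction times are drawn log-normally, `log(RT) ~ Normal(baseline_log_ms +
#' slope_per_degree * angle, sd_log)`, truncated to `[1, stimulus_timeout]` ms;
#' draws beyond the timeout become timeout trials without a response.
#' Correctness is Bernoulli with the angle's accuracy; timeout trials count as
#' missing responses (`correct = FALSE`). Event sample indices (0-based, 1
#' sample = 1 ms at 1 kHz) are laid out chronologically with a 1 s lead-in.
#'
#' @param schedule output of [generate_schedule()].
#' @param config the same [sim_config()].
#' @return completed trial table with columns `reaction_time_ms`, `timeout`,
#'   `correct`, `fixation_onset`, `stimulus_onset`, `response_sample`.
#' @export
simulate_behaviour <- function(schedule, config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "behaviour"))
  n <- nrow(schedule)
  mu <- config$rt_model$baseline_log_ms +
    config$rt_model$slope_per_degree * schedule$angle
  rt <- exp(rnorm(n, mu, config$rt_model$sd_log))
  rt <- pmax(rt, 1)
  timeout <- rt > config$stimulus_timeout
  rt[timeout] <- config$stimulus_timeout
  rt <- as.integer(round(rt))
  acc <- config$accuracy_by_angle[match(schedule$angle, config$angles)]
  correct <- rbinom(n, 1, acc) == 1
  correct[timeout] <- FALSE

  ms_per_sample <- 1000 / config$sampling_rate
  lead_in <- as.integer(round(1000 / ms_per_sample))
  fix_len <- as.integer(round(schedule$fixation_duration_ms / ms_per_sample))
  stim_len <- as.integer(round(rt / ms_per_sample))
  fixation_onset <- integer(n)
  stimulus_onset <- integer(n)
  cursor <- lead_in
  for (i in seq_len(n)) {
    fixation_onset[i] <- cursor
    stimulus_onset[i] <- cursor + fix_len[i]
    cursor <- stimulus_onset[i] + stim_len[i]
  }
  out <- schedule
  out$reaction_time_ms <- rt
  out$timeout <- timeout
  out$correct <- correct
  out$fixation_onset <- fixation_onset
  out$stimulus_onset <- stimulus_onset
  out$response_sample <- ifelse(timeout, NA_integer_, stimulus_onset + stim_len)
  out$stimulus_end <- stimulus_onset + stim_len
  out
}

# Piecewise-exact variance rescaling: scales u inside each [start, end) window
# (1-based inclusive start, exclusive end) to the matching target variance and
# every gap segment to the baseline variance. Returns the scaled series plus
# the realized epoch variances.
rescale_windows <- function(u, starts, len, targets, baseline_var) {
  n <- length(u)
  gain <- numeric(0)
  realized <- numeric(length(starts))
  out <- u
  prev_end <- 0L
  scale_seg <- function(seg, target) {
    v <- mean(seg^2) - mean(seg)^2
    if (v <= 0) return(seg)
    seg * sqrt(target / v)
  }
  for (e in seq_along(starts)) {
    s <- starts[e] + 1L   # to 1-based
    if (s > prev_end + 1L) {
      idx <- (prev_end + 1L):(s - 1L)
      out[idx] <- scale_seg(u[idx], baseline_var)
    }
    idx <- s:(s + len - 1L)
    out[idx] <- scale_seg(u[idx], targets[e])
    realized[e] <- mean(out[idx]^2) - mean(out[idx])^2
    prev_end <- s + len - 1L
  }
  if (prev_end < n) {
    idx <- (prev_end + 1L):n
    out[idx] <- scale_seg(u[idx], baseline_var)
  }
  list(series = out, realized = realized)
}

# Topographies of the planted sources, shared between the task and the
# resting-state session of one participant (drawn from a dedicated substream).
planted_topographies <- function(config, participant = 0L) {
  set.seed(substream_seed(config$seed, "topos", participant))
  lapply(config$source_specs, function(sp) {
    sp$topography %||% unit_norm(rnorm(config$n_channels))
  })
}

blink_waveform <- function(duration_samples, amplitude) {
  amplitude * sin(pi * seq(0, 1, length.out = duration_samples))^2
}

blink_topography <- function(labels) {
  w <- setNames(numeric(length(labels)), labels)
  frontal <- c(Fp1 = 1, Fp2 = 1, F7 = 0.45, F3 = 0.55, Fz = 0.5, F4 = 0.55,
               F8 = 0.45, FC1 = 0.2, FC2 = 0.2)
  for (nm in names(frontal)) if (nm %in% labels) w[nm] <- frontal[[nm]]
  if (all(w == 0)) w[1] <- 1   # montages without frontal labels
  unname(unit_norm(w))
}

add_blinks <- function(sig, times, duration_samples, amplitude, topo) {
  wave <- blink_waveform(duration_samples, amplitude)
  n <- ncol(sig)
  tc <- numeric(n)
  for (t0 in times) {
    idx <- (t0 + 1):min(t0 + duration_samples, n)
    tc[idx] <- tc[idx] + wave[seq_along(idx)]
  }
  sig + topo %*% t(tc)
}

#' Synthesize the task-session EEG for a completed trial table
#'
#' The signal is a sum of (a) planted band-limited sources, each FIR-filtered
#' white noise rescaled piecewise so that its variance inside every stimulus
#' epoch window `[stimulus_onset, stimulus_onset + 500 ms)` equals exactly
#' `exp(baseline_log_variance + comodulation * z)` (with `z` the standardized
#' log RT across trials) and equals the baseline variance between epochs,
#' (b) broadband background sources, (c) white sensor noise per channel, and
#' (d) optional stereotyped blink transients with a fixed frontal topography.
#' All planted quantities are recorded in `ground_truth`.
#'
#' @param trials completed trial table from [simulate_behaviour()].
#' @param config the [sim_config()].
#' @param participant participant index used for substream derivation.
#' @return a `raw_session`: `signal` (channels x samples, uV),
#'   `sampling_rate`, `channel_labels`, `events` data.frame, `trials`,
#'   `ground_truth`.
#' @export
synthesize_eeg <- function(trials, config, participant = 0L) {
  validate_sim_config(config)
  if (is.null(trials$reaction_time_ms)) {
    stop("trial table lacks behaviour; run simulate_behaviour() first")
  }
  ms_per_sample <- 1000 / config$sampling_rate
  epoch_len <- as.integer(round(500 / ms_per_sample))
  n_samples <- max(trials$stimulus_end) + as.integer(round(1000 / ms_per_sample))
  n_ch <- config$n_channels
  labels <- montage_labels(n_ch)

  z <- zscore_pop(log(trials$reaction_time_ms))

  topos <- planted_topographies(config, participant)
  set.seed(substream_seed(config$seed, "sources", participant))
  sig <- matrix(0, n_ch, n_samples)
  src_truth <- list()
  for (k in seq_along(config$source_specs)) {
    sp <- config$source_specs[[k]]
    topo <- topos[[k]]
    bd <- design_band_filter(sp$band_center, sp$band_width,
                             config$sampling_rate, n_taps = 501L)
    u <- fir_filtfilt(rnorm(n_samples), bd$taps)
    targets <- exp(sp$baseline_log_variance + sp$comodulation * z)
    rs <- rescale_windows(u, trials$stimulus_onset, epoch_len, targets,
                          exp(sp$baseline_log_variance))
    sig <- sig + topo %*% t(rs$series)
    src_truth[[k]] <- list(
      band_center = sp$band_center, band_width = sp$band_width,
      baseline_log_variance = sp$baseline_log_variance,
      comodulation = sp$comodulation, topography = topo,
      target_variance = targets, realized_variance = rs$realized
    )
  }

  set.seed(substream_seed(config$seed, "background", participant))
  bg_topos <- NULL
  if (config$n_background > 0) {
    bg_topos <- vapply(seq_len(config$n_background),
                       function(i) unit_norm(rnorm(n_ch)), numeric(n_ch))
    bg <- matrix(rnorm(config$n_background * n_samples, sd = config$background_sd),
                 config$n_background, n_samples)
    sig <- sig + bg_topos %*% bg
  }

  set.seed(substream_seed(config$seed, "noise", participant))
  if (config$noise_sd > 0) {
    sig <- sig + matrix(rnorm(n_ch * n_samples, sd = config$noise_sd),
                        n_ch, n_samples)
  }

  blink_times <- integer(0)
  topo_blink <- blink_topography(labels)
  if (isTRUE(config$artifact$in_task) && config$artifact$rate_per_min > 0) {
    set.seed(substream_seed(config$seed, "artifacts", participant))
    dur <- as.integer(round(config$artifact$duration_ms / ms_per_sample))
    n_blinks <- rpois(1, config$artifact$rate_per_min * n_samples /
                        (60 * config$sampling_rate))
    if (n_blinks > 0) {
      blink_times <- sort(sample.int(n_samples - dur, n_blinks))
      sig <- add_blinks(sig, blink_times, dur, config$artifact$amplitude,
                        topo_blink)
    }
  }

  events <- build_events(trials)
  session <- structure(
    list(signal = sig, sampling_rate = config$sampling_rate,
         channel_labels = labels, events = events, trials = trials,
         ground_truth = list(
           sources = src_truth, z = z,
           background_topographies = bg_topos,
           blink_topography = topo_blink, blink_times = blink_times,
           epoch_length = epoch_len
         )),
    class = "raw_session"
  )
  stopifnot_finite(session$signal, "synthesized signal")
  session
}

build_events <- function(trials) {
  n <- nrow(trials)
  ev <- rbind(
    data.frame(sample = trials$fixation_onset, marker = "fixation_on",
               trial_index = trials$trial_index),
    data.frame(sample = trials$stimulus_onset, marker = "stimulus_on",
               trial_index = trials$trial_index),
    data.frame(sample = trials$stimulus_end,
               marker = ifelse(trials$timeout, "timeout", "response"),
               trial_index = trials$trial_index)
  )
  ev <- ev[order(ev$sample, ev$trial_index), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Generate a one-minute eyes-open resting-state session
#'
#' Contains the planted oscillatory sources at their baseline variance, the
#' broadband background sources, sensor noise, and blink transients at the
#' configured rate. Ground truth stores the blink topography and event times.
#'
#' @param config a [sim_config()].
#' @param participant participant index for substream derivation.
#' @param duration_s duration in seconds (60 by default).
#' @return a `raw_session` without trials.
#' @export
generate_resting_state <- function(config, participant = 0L, duration_s = 60) {
  validate_sim_config(config)
  n_samples <- as.integer(round(duration_s * config$sampling_rate))
  n_ch <- config$n_channels
  labels <- montage_labels(n_ch)
  topos <- planted_topographies(config, participant)
  set.seed(substream_seed(config$seed, "resting", participant))
  sig <- matrix(0, n_ch, n_samples)
  src_topos <- list()
  for (k in seq_along(config$source_specs)) {
    sp <- config$source_specs[[k]]
    topo <- topos[[k]]
    bd <- design_band_filter(sp$band_center, sp$band_width,
                             config$sampling_rate, n_taps = 501L)
    u <- fir_filtfilt(rnorm(n_samples), bd$taps)
    v <- mean(u^2) - mean(u)^2
    u <- u * sqrt(exp(sp$baseline_log_variance) / v)
    sig <- sig + topo %*% t(u)
    src_topos[[k]] <- topo
  }
  if (config$n_background > 0) {
    bg_topos <- vapply(seq_len(config$n_background),
                       function(i) unit_norm(rnorm(n_ch)), numeric(n_ch))
    sig <- sig + bg_topos %*%
      matrix(rnorm(config$n_background * n_samples, sd = config$background_sd),
             config$n_background, n_samples)
  }
  if (config$noise_sd > 0) {
    sig <- sig + matrix(rnorm(n_ch * n_samples, sd = config$noise_sd),
                        n_ch, n_samples)
  }
  topo_blink <- blink_topography(labels)
  blink_times <- integer(0)
  if (config$artifact$rate_per_min > 0) {
    ms_per_sample <- 1000 / config$sampling_rate
    dur <- as.integer(round(config$artifact$duration_ms / ms_per_sample))
    n_blinks <- rpois(1, config$artifact$rate_per_min * duration_s / 60)
    if (n_blinks > 0) {
      blink_times <- sort(sample.int(n_samples - dur, n_blinks))
      sig <- add_blinks(sig, blink_times, dur, config$artifact$amplitude,
                        topo_blink)
    }
  }
  structure(
    list(signal = sig, sampling_rate = config$sampling_rate,
         channel_labels = labels,
         events = data.frame(sample = integer(0), marker = character(0),
                             trial_index = integer(0)),
         trials = NULL,
         ground_truth = list(
           source_topographies = src_topos,
           blink_topography = topo_blink, blink_times = blink_times
         )),
    class = "raw_session"
  )
}

#' Simulate one full participant (task session plus resting state)
#'
#' @param config a [sim_config()].
#' @param participant participant index (also offsets the substreams).
#' @return list with `task` and `resting` raw sessions and the completed
#'   `trials` table.
#' @export
simulate_participant <- function(config, participant = 0L) {
  cfg <- config
  # participant-specific randomness flows through the substream offsets; the
  # schedule/behaviour streams are offset too so participants differ.
  cfg$seed <- substream_seed(config$seed, "misc", participant)
  schedule <- generate_schedule(cfg)
  trials <- simulate_behaviour(schedule, cfg)
  task <- synthesize_eeg(trials, cfg, participant)
  resting <- generate_resting_state(cfg, participant)
  list(task = task, resting = resting, trials = trials, config = cfg)
}
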