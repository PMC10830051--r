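# Minimal EDF (European Data Format) codec: 16-bit integer encoding, one
# 1-second data record per block, ASCII headers. Only the subset needed to
# round-trip continuous multichannel EEG is implemented; the exact sample
# count (EDF pads the final record) travels in the recording.json sidecar.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

write_edf <- function(signal, sampling_rate, channel_labels, path) {
  n_ch <- nrow(signal)
  n <- ncol(signal)
  rec_len <- as.integer(sampling_rate)
  n_rec <- ceiling(n / rec_len)
  pad_n <- n_rec * rec_len - n
  if (pad_n > 0) signal <- cbind(signal, matrix(0, n_ch, pad_n))

  phys_min <- apply(signal, 1, min)
  phys_max <- apply(signal, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("synthetic participant", 80),
    pad_field("synthetic EEG session", 80),
    pad_field("01.01.24", 8), pad_field("00.00.00", 8),
    pad_field(256 * (n_ch + 1), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(n_ch, 4)
  )
  sig_hdr <- paste0(
    paste0(vapply(channel_labels, pad_field, "", width = 16), collapse = ""),
    paste0(rep(pad_field("EEG", 80), n_ch), collapse = ""),
    paste0(rep(pad_field("uV", 8), n_ch), collapse = ""),
    paste0(vapply(sprintf("%.6g", phys_min), pad_field, "", width = 8), collapse = ""),
    paste0(vapply(sprintf("%.6g", phys_max), pad_field, "", width = 8), collapse = ""),
    paste0(rep(pad_field(dig_min, 8), n_ch), collapse = ""),
    paste0(rep(pad_field(dig_max, 8), n_ch), collapse = ""),
    paste0(rep(pad_field("", 80), n_ch), collapse = ""),
    paste0(rep(pad_field(rec_len, 8), n_ch), collapse = ""),
    paste0(rep(pad_field("", 32), n_ch), collapse = "")
  )
  writeBin(charToRaw(paste0(hdr, sig_hdr)), con)

  gain <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * rec_len + 1):(r * rec_len)
    block <- signal[, cols, drop = FALSE]
    dig <- round((block - phys_min) * gain + dig_min)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  if (nchar(hdr) < 256 || trimws(substr(hdr, 1, 8)) != "0") {
    stop("corrupted or unsupported EDF header in ", path)
  }
  n_rec <- as.integer(trimws(substr(hdr, 237, 244)))
  rec_dur <- as.numeric(trimws(substr(hdr, 245, 252)))
  n_ch <- as.integer(trimws(substr(hdr, 253, 256)))
  if (is.na(n_rec) || is.na(n_ch) || n_ch <= 0 || n_rec < 0) {
    stop("corrupted EDF header fields in ", path)
  }
  sh_raw <- readBin(con, "raw", 256 * n_ch)
  if (length(sh_raw) < 256 * n_ch || any(sh_raw > as.raw(127))) {
    stop("corrupted EDF signal header in ", path)
  }
  sh <- rawToChar(sh_raw)
  field <- function(offset, width) {
    vapply(seq_len(n_ch), function(i) {
      trimws(substr(sh, offset * n_ch + (i - 1) * width + 1,
                    offset * n_ch + i * width))
    }, "")
  }
  labels <- field(0, 16)
  # offsets in bytes within the signal header: labels 16, transducer 80,
  # units 8, phys_min 8, phys_max 8, dig_min 8, dig_max 8, prefilter 80, ns 8
  off <- cumsum(c(0, 16, 80, 8, 8, 8, 8, 8, 80))
  at <- function(k, width) {
    vapply(seq_len(n_ch), function(i) {
      trimws(substr(sh, off[k] * n_ch + (i - 1) * width + 1,
                    off[k] * n_ch + i * width))
    }, "")
  }
  phys_min <- as.numeric(at(4, 8))
  phys_max <- as.numeric(at(5, 8))
  dig_min <- as.numeric(at(6, 8))
  dig_max <- as.numeric(at(7, 8))
  rec_len <- as.integer(at(9, 8))
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, rec_len)))) {
    stop("corrupted EDF signal header fields in ", path)
  }
  sig <- matrix(0, n_ch, n_rec * rec_len[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw_block <- readBin(con, "integer", n_ch * rec_len[1], size = 2,
                         signed = TRUE, endian = "little")
    if (length(raw_block) < n_ch * rec_len[1]) stop("truncated EDF data in ", path)
    block <- matrix(raw_block, nrow = rec_len[1])
    cols <- ((r - 1) * rec_len[1] + 1):(r * rec_len[1])
    sig[, cols] <- t((block - rep(dig_min, each = rec_len[1])) *
                       rep(gain, each = rec_len[1]) +
                       rep(phys_min, each = rec_len[1]))
  }
  list(signal = sig, channel_labels = labels,
       sampling_rate = rec_len[1] / rec_dur)
}

#' Write a session to disk (EDF + BIDS-style sidecars)
#'
#' Writes `<prefix>_eeg.edf` (16-bit EDF), `<prefix>_events.tsv` (columns
#' `onset` in seconds, `duration`, `sample`, `trial_type`, `trial_index` plus,
#' on `stimulus_on` rows, `angle`, `mirrored`, `response`, `reaction_time_ms`,
#' `correct`), `<prefix>_channels.tsv` (`name`, `type`, `units`),
#' `<prefix>_recording.json` (exact sample count and sampling rate) and
#' `<prefix>_ground_truth.json`.
#'
#' @param session a `raw_session`.
#' @param directory output directory (created if missing).
#' @param prefix file-name prefix, e.g. `"sub-01_task-rotation"`.
#' @return invisibly, the vector of files written.
#' @export
write_session <- function(session, directory, prefix = "session") {
  stopifnot(inherits(session, "raw_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(directory, paste0(prefix, suffix))

  write_edf(session$signal, session$sampling_rate, session$channel_labels,
            p("_eeg.edf"))

  ev <- session$events
  fs <- session$sampling_rate
  tr <- session$trials
  n_ev <- nrow(ev)
  evt <- data.frame(
    onset = ev$sample / fs,
    duration = rep(0, n_ev),
    sample = ev$sample,
    trial_type = ev$marker,
    trial_index = ev$trial_index,
    angle = rep(NA_real_, n_ev), mirrored = rep(NA, n_ev),
    response = rep(NA_character_, n_ev),
    reaction_time_ms = rep(NA_integer_, n_ev), correct = rep(NA, n_ev)
  )
  if (!is.null(tr)) {
    i <- match(evt$trial_index, tr$trial_index)
    stim <- evt$trial_type == "stimulus_on"
    evt$angle[stim] <- tr$angle[i][stim]
    evt$mirrored[stim] <- tr$mirrored[i][stim]
    evt$reaction_time_ms[stim] <- tr$reaction_time_ms[i][stim]
    evt$correct[stim] <- tr$correct[i][stim]
    evt$response[stim] <- ifelse(tr$timeout[i][stim], "none",
                                 ifelse(tr$correct[i][stim], "correct", "incorrect"))
    evt$duration[stim] <-(tr$stimulus_end[i][stim] - tr$stimulus_onset[i][stim]) / fs
    fix <- evt$trial_type == "fixation_on"
    evt$duration[fix] <- (tr$stimulus_onset[i][fix] - tr$fixation_onset[i][fix]) / fs
  }
  write.table(evt, p("_events.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "n/a")

  chan <- data.frame(name = session$channel_labels, type = "EEG", units = "uV")
  write.table(chan, p("_channels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  jsonlite::write_json(
    list(sampling_rate = session$sampling_rate,
         n_samples = ncol(session$signal),
         n_channels = nrow(session$signal)),
    p("_recording.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(session$ground_truth)) {
    jsonlite::write_json(session$ground_truth, p("_ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(c(p("_eeg.edf"), p("_events.tsv"), p("_channels.tsv"),
              p("_recording.json"), p("_ground_truth.json")))
}

#' Read a session written by [write_session()]
#'
#' @param directory directory containing the files.
#' @param prefix the file-name prefix used when writing.
#' @return a `raw_session`; signal values agree with the written session up to
#'   EDF 16-bit quantization, metadata exactly.
#' @export
read_session <- function(directory, prefix = "session") {
  p <- function(suffix) file.path(directory, paste0(prefix, suffix))
  for (f in c("_eeg.edf", "_events.tsv", "_channels.tsv", "_recording.json")) {
    if (!file.exists(p(f))) stop("missing session file: ", p(f))
  }
  rec <- jsonlite::read_json(p("_recording.json"), simplifyVector = TRUE)
  edf <- read_edf(p("_eeg.edf"))
  if (ncol(edf$signal) < rec$n_samples) {
    stop("inconsistent sample counts between EDF and recording.json: ",
         p("_eeg.edf"))
  }
  sig <- edf$signal[, seq_len(rec$n_samples), drop = FALSE]
  chan <- read.delim(p("_channels.tsv"))
  evt <- read.delim(p("_events.tsv"), na.strings = "n/a")
  events <- data.frame(sample = evt$sample, marker = evt$trial_type,
                       trial_index = evt$trial_index)
  trials <- NULL
  stim <- evt[evt$trial_type == "stimulus_on", , drop = FALSE]
  if (nrow(stim) > 0) {
    resp <- evt[evt$trial_type %in% c("response", "timeout"), , drop = FALSE]
    fix <- evt[evt$trial_type == "fixation_on", , drop = FALSE]
    i <- order(stim$trial_index)
    stim <- stim[i, ]
    resp <- resp[order(resp$trial_index), ]
    fix <- fix[order(fix$trial_index), ]
    trials <- data.frame(
      trial_index = stim$trial_index,
      angle = stim$angle,
      mirrored = as.logical(stim$mirrored),
      fixation_onset = fix$sample,
      stimulus_onset = stim$sample,
      reaction_time_ms = stim$reaction_time_ms,
      timeout = resp$trial_type == "timeout",
      correct = as.logical(stim$correct),
      stimulus_end = resp$sample
    )
    trials$response_sample <- ifelse(trials$timeout, NA_integer_, trials$stimulus_end)
    trials <- trials[order(trials$trial_index), ]
    rownames(trials) <- NULL
  }
  gt <- NULL
  if (file.exists(p("_ground_truth.json"))) {
    gt <- jsonlite::read_json(p("_ground_truth.json"), simplifyVector = TRUE)
  }
  structure(
    list(signal = sig, sampling_rate = rec$sampling_rate,
         channel_labels = chan$name, events = events, trials = trials,
         ground_truth = gt),
    class = "raw_session"
  )
}
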