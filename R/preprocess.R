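#' Fit an ICA decomposition on a resting-state session
#'
#' A 1 Hz high-pass filtered copy of the recording is used for estimation (the
#' decomposition is later applied to the raw, unfiltered signal). Channels are
#' PCA-whitened and unmixed with symmetric FastICA (tanh contrast); one
#' component per channel. Deterministic given the seed. Gaussian subspaces
#' are rotation-indeterminate for ICA, so the fixed-point iteration need not
#' reach `tol` on largely Gaussian recordings; identifiable (non-Gaussian)
#' components stabilize within tens of iterations and the capped iteration
#' keeps the result deterministic either way.
#'
#' @param resting a `raw_session` of at least 10 s.
#' @param seed integer seed for the random orthonormal initialization.
#' @param max_iter,tol FastICA iteration controls.
#' @param decimate keep every k-th sample for estimation (the unmixing matrix
#'   acts on channels, so estimation on a decimated copy is statistically
#'   equivalent for band-limited sources; 1 = no decimation).
#' @return an `ica_decomposition`: `unmixing` (components x channels),
#'   `mixing` (channels x components, pseudo-inverse), `rejected` (empty).
#' @export
fit_ica <- function(resting, seed = 1L, max_iter = 100L, tol = 1e-4,
                    decimate = 4L) {
  stopifnot(inherits(resting, "raw_session"))
  n <- ncol(resting$signal)
  if (n < 10 * resting$sampling_rate) stop("resting session shorter than 10 s")
  hp <- highpass_1hz(resting$signal, resting$sampling_rate)
  x <- hp[, seq(1, n, by = decimate), drop = FALSE]
  n_ch <- nrow(x)
  x <- x - rowMeans(x)
  C <- x %*% t(x) / (ncol(x) - 1)
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values < 1e-10 * eg$values[1])) {
    bad <- which(eg$values < 1e-10 * eg$values[1])
    qrp <- qr(t(x), LAPACK = TRUE)
    dep <- sort(qrp$pivot[(qrp$rank + 1):n_ch])
    stop("rank-deficient input: ", length(bad), " degenerate dimension(s); ",
         "linearly dependent channels: ",
         paste(resting$channel_labels[dep], collapse = ", "))
  }
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)   # whitening: K x -> white
  xw <- K %*% x

  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(n_ch * n_ch), n_ch)))
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values)) %*% t(s$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  m <- ncol(xw)
  for (it in seq_len(max_iter)) {
    wx <- W %*% xw
    gx <- tanh(wx)
    gpx <- rowMeans(1 - gx^2)
    W_new <- gx %*% t(xw) / m - diag(gpx) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) break
  }
  unmixing <- W %*% K
  mixing <- MASS_ginv(unmixing)
  structure(
    list(unmixing = unmixing, mixing = mixing, rejected = integer(0),
         channel_labels = resting$channel_labels, iterations = it,
         converged = delta < tol),
    class = "ica_decomposition"
  )
}

# Moore-Penrose pseudo-inverse via SVD (only used for the square unmixing
# matrix, where it is the plain inverse up to numerical rank handling).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

highpass_1hz <- function(sig, sampling_rate) {
  bt <- signal::butter(4, 1 / (sampling_rate / 2), type = "high")
  out <- sig
  for (ch in seq_len(nrow(sig))) {
    out[ch, ] <- signal::filtfilt(bt, sig[ch, ])
  }
  out
}

#' Select artifact components for rejection
#'
#' Config-first: if `reject` lists component indices they are returned
#' verbatim. Otherwise components are flagged automatically when their
#' resting-state time course correlates (absolute Pearson r at or above
#' `threshold`) with a blink reference: the low-frequency (< 5 Hz) envelope of
#' the frontal channels (Fp1/Fp2, falling back to the first two channels).
#'
#' @param ica an `ica_decomposition`.
#' @param resting the resting-state `raw_session` the ICA was fitted on.
#' @param reject explicit integer vector of component indices (1-based), or
#'   `NULL` for automatic selection.
#' @param threshold absolute-correlation threshold for automatic flagging.
#' @return integer vector of component indices to reject (possibly empty).
#' @export
select_artifact_components <- function(ica, resting, reject = NULL,
                                       threshold = 0.8) {
  if (!is.null(reject)) return(as.integer(reject))
  frontal <- which(ica$channel_labels %in% c("Fp1", "Fp2"))
  if (length(frontal) == 0) frontal <- seq_len(min(2, nrow(resting$signal)))
  lp <- signal::butter(4, 5 / (resting$sampling_rate / 2), type = "low")
  ref <- signal::filtfilt(lp, colMeans(resting$signal[frontal, , drop = FALSE]))
  comps <- ica$unmixing %*% resting$signal
  r <- abs(apply(comps, 1, function(tc) suppressWarnings(cor(tc, ref))))
  r[is.na(r)] <- 0
  which(r >= threshold)
}

#' Apply ICA cleaning to a raw session
#'
#' Projects the raw, unfiltered signal onto the ICA components, zeroes the
#' rejected component time courses (equivalently: zeroes the corresponding
#' columns of the mixing step), and reconstructs the channels.
#'
#' @param raw a `raw_session`.
#' @param ica an `ica_decomposition`.
#' @param rejected integer component indices to remove; defaults to
#'   `ica$rejected`.
#' @return the cleaned `raw_session`.
#' @export
apply_ica_cleaning <- function(raw, ica, rejected = ica$rejected) {
  if (nrow(raw$signal) != ncol(ica$unmixing)) {
    stop("channel count mismatch between session (", nrow(raw$signal),
         ") and ICA (", ncol(ica$unmixing), ")")
  }
  # cleaned = mixing %*% (unmixing %*% signal with rejected rows zeroed);
  # fused into one channels x channels projection for speed.
  U <- ica$unmixing
  if (length(rejected) > 0) U[rejected, ] <- 0
  out <- raw
  out$signal <- (ica$mixing %*% U) %*% raw$signal
  out$ica_rejected <- as.integer(rejected)
  out
}

#' Epoch band-filtered sessions by presentation-phase markers
#'
#' One epoch per presentation phase: fixation epochs span
#' `[fixation_on, stimulus_on)` and stimulus epochs `[stimulus_on,
#' response-or-timeout)`, half-open, 0-based. A complete session of `n` trials
#' yields `2 n` epochs before any removal.
#'
#' @param band_sessions list of band-filtered `raw_session` objects (from
#'   [apply_filter_bank()]); a single `raw_session` is accepted too.
#' @return an `epoch_set` with ragged (channels x time) epoch matrices per
#'   band and a metadata table (one row per epoch).
#' @export
epoch_session <- function(band_sessions) {
  if (inherits(band_sessions, "raw_session")) band_sessions <- list(band_sessions)
  s1 <- band_sessions[[1]]
  ev <- s1$events
  tr <- s1$trials
  if (is.null(tr)) stop("session has no trial table; cannot epoch")
  for (idx in tr$trial_index) {
    sub <- ev[ev$trial_index == idx, ]
    if (sum(sub$marker == "fixation_on") != 1 ||
        sum(sub$marker == "stimulus_on") != 1 ||
        sum(sub$marker %in% c("response", "timeout")) != 1) {
      stop("orphan or duplicate markers for trial ", idx)
    }
  }
  meta <- rbind(
    data.frame(trial_index = tr$trial_index, phase = "fixation",
               start = tr$fixation_onset, end = tr$stimulus_onset),
    data.frame(trial_index = tr$trial_index, phase = "stimulus",
               start = tr$stimulus_onset, end = tr$stimulus_end)
  )
  meta <- meta[order(meta$start), ]
  rownames(meta) <- NULL
  i <- match(meta$trial_index, tr$trial_index)
  meta$angle <- tr$angle[i]
  meta$mirrored <- tr$mirrored[i]
  meta$reaction_time_ms <- tr$reaction_time_ms[i]
  meta$correct <- tr$correct[i]
  meta$timeout <- tr$timeout[i]
  data <- lapply(band_sessions, function(bs) {
    lapply(seq_len(nrow(meta)), function(e) {
      bs$signal[, (meta$start[e] + 1):(meta$end[e]), drop = FALSE]
    })
  })
  structure(
    list(data = data, meta = meta,
         bands = lapply(band_sessions, function(bs) bs$band),
         sampling_rate = s1$sampling_rate,
         channel_labels = s1$channel_labels, cropped = FALSE),
    class = "epoch_set"
  )
}

#' Apply the epoch-retention and cropping rules
#'
#' Removes (a) fixation epochs, (b) epochs with incorrect or missing (timeout)
#' responses, (c) epochs with a reaction time below `min_rt_ms`, then crops
#' every retained epoch to its initial `crop_ms`. Because retained responses
#' come at `min_rt_ms` or later, the retained window never overlaps the final
#' 200 ms before the response (motor preparation), which is asserted.
#'
#' @param epochs an uncropped `epoch_set`.
#' @param min_rt_ms minimal reaction time in ms (epochs below are dropped).
#' @param crop_ms retained window length in ms from stimulus onset.
#' @return a cropped `epoch_set` with arrays `[epoch, channel, time]` per band
#'   and a `removal_counts` attribute with per-rule provenance.
#' @export
filter_and_crop_epochs <- function(epochs, min_rt_ms = 700, crop_ms = 500) {
  stopifnot(inherits(epochs, "epoch_set"), !epochs$cropped)
  meta <- epochs$meta
  rule_fixation <- meta$phase == "fixation"
  rule_incorrect <- !rule_fixation & (!meta$correct | meta$timeout)
  rule_short <- !rule_fixation & !rule_incorrect & meta$reaction_time_ms < min_rt_ms
  keep <- !(rule_fixation | rule_incorrect | rule_short)
  counts <- c(total = nrow(meta), fixation = sum(rule_fixation),
              incorrect_or_missing = sum(rule_incorrect),
              too_early = sum(rule_short), retained = sum(keep))
  n_keep <- sum(keep)
  if (n_keep == 0) warning("no epochs retained after filtering")
  len <- as.integer(round(crop_ms * epochs$sampling_rate / 1000))
  guard_ms <- 200
  stopifnot(all(meta$reaction_time_ms[keep] - guard_ms >= crop_ms))
  n_ch <- length(epochs$channel_labels)
  data <- lapply(epochs$data, function(band) {
    arr <- array(0, c(n_keep, n_ch, len))
    ki <- which(keep)
    for (j in seq_along(ki)) arr[j, , ] <- band[[ki[j]]][, seq_len(len)]
    arr
  })
  out_meta <- meta[keep, , drop = FALSE]
  rownames(out_meta) <- NULL
  structure(
    list(data = data, meta = out_meta, bands = epochs$bands,
         sampling_rate = epochs$sampling_rate,
         channel_labels = epochs$channel_labels, cropped = TRUE,
         removal_counts = counts),
    class = "epoch_set"
  )
}

#' Write / read an epochs container
#'
#' The container is stored as a single R-native serialized file with fixed
#' element names (`data`, `meta`, `bands`, ...), mirroring a hierarchical
#' dataset layout.
#'
#' @param epochs an `epoch_set`.
#' @param path file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` the
#'   `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("missing epochs file: ", path)
  out <- readRDS(path)
  stopifnot(inherits(out, "epoch_set"))
  out
}
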