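#' Band definitions for the ten-band filter bank
#'
#' Builds the filter bank used for band-power feature extraction: 4 Hz-wide
#' Hamming-windowed linear-phase FIR band-pass filters with centres at
#' 2, 6, ..., 38 Hz. The lowest band (centre 2 Hz) has its lower edge at 0 Hz
#' and is designed as a low-pass at 4 Hz. Filters are applied zero-phase in a
#' single pass with group-delay compensation (the taps are symmetric).
#'
#' @param centers band centre frequencies in Hz. Default `seq(2, 38, by = 4)`.
#' @param width band width in Hz (edges at centre +- width/2).
#' @param sampling_rate sampling rate in Hz.
#' @param n_taps odd FIR length. The default (501 taps at 1 kHz) passes a
#'   centre-frequency sinusoid with gain 1 +- 0.003 and attenuates a tone 6 Hz
#'   outside the band by more than 40 dB.
#' @return list of `band_definition` objects with fields `center`, `low`,
#'   `high`, `taps`, `index`.
#' @export
band_definitions <- function(centers = seq(2, 38, by = 4), width = 4,
                             sampling_rate = 1000, n_taps = 501) {
  lapply(seq_along(centers), function(i) {
    design_band_filter(centers[i], width, sampling_rate, n_taps, index = i - 1L)
  })
}

#' Design one Hamming-windowed FIR band-pass filter
#'
#' @inheritParams band_definitions
#' @param center centre frequency in Hz.
#' @param index band index (0-based), stored for bookkeeping.
#' @return a `band_definition` list.
#' @export
design_band_filter <- function(center, width = 4, sampling_rate = 1000,
                               n_taps = 501, index = 0L) {
  lo <- center - width / 2
  hi <- center + width / 2
  nyq <- sampling_rate / 2
  if (hi >= nyq) stop("band edge ", hi, " Hz at or above Nyquist (", nyq, " Hz)")
  if (n_taps %% 2 != 1) stop("n_taps must be odd (type-I linear phase)")
  taps <- if (lo <= 0) {
    signal::fir1(n_taps - 1, hi / nyq, type = "low", window = signal::hamming(n_taps))
  } else {
    signal::fir1(n_taps - 1, c(lo, hi) / nyq, type = "pass", window = signal::hamming(n_taps))
  }
  structure(
    list(center = center, low = max(lo, 0), high = hi,
         taps = as.numeric(taps), index = as.integer(index),
         sampling_rate = sampling_rate),
    class = "band_definition"
  )
}

# Zero-phase FIR filtering of a vector: symmetric taps applied in one pass,
# output shifted back by the group delay (L-1)/2. Edges are reflect-padded by
# one filter length and trimmed after compensation. FFT-based convolution.
fir_filtfilt <- function(x, taps) {
  L <- length(taps)
  stopifnot(L %% 2 == 1)
  d <- (L - 1) / 2
  n <- length(x)
  if (n < 2) stop("signal too short to filter")
  pad <- min(L, n - 1)
  xp <- c(x[(pad + 1):2], x, x[n - seq_len(pad)])
  m <- length(xp) + L - 1
  nfft <- nextn(m, 2)
  X <- fft(c(xp, numeric(nfft - length(xp))))
  H <- fft(c(taps, numeric(nfft - L)))
  y <- Re(fft(X * H, inverse = TRUE)) / nfft
  # full convolution y[k] = sum taps[j] xp[k-j+1]; zero-phase output at sample t
  # of xp is y[t + d]; drop the reflected padding.
  y[(pad + d + 1):(pad + d + n)]
}

# Zero-phase filter every row (channel) of a channels x samples matrix.
fir_filtfilt_mat <- function(sig, taps) {
  out <- sig
  for (ch in seq_len(nrow(sig))) out[ch, ] <- fir_filtfilt(sig[ch, ], taps)
  out
}

#' Apply the filter bank to a raw session
#'
#' Returns one band-filtered copy of the session per band, each filtered
#' zero-phase (group-delay compensated single pass, reflect-padded edges).
#'
#' @param raw a `raw_session` (see [synthesize_eeg()]).
#' @param bands list of `band_definition` objects.
#' @return list of `raw_session` objects, one per band, with a `band` field.
#' @export
apply_filter_bank <- function(raw, bands) {
  stopifnot(inherits(raw, "raw_session"))
  nyq <- raw$sampling_rate / 2
  for (b in bands) if (b$high >= nyq) stop("band edge above Nyquist")
  lapply(bands, function(b) {
    out <- raw
    out$signal <- fir_filtfilt_mat(raw$signal, b$taps)
    out$band <- b
    out
  })
}

# Banded Toeplitz operator T (out_len x (out_len + L - 1)) such that
# T %*% seg equals the zero-phase filter output on a window, where seg is the
# input window extended by (L-1)/2 samples on both sides.
toeplitz_filter_operator <- function(taps, out_len) {
  L <- length(taps)
  A <- matrix(0, out_len, out_len + L - 1)
  rv <- rev(taps)
  for (i in seq_len(out_len)) A[i, i:(i + L - 1)] <- rv
  A
}

# Filter-and-epoch fast path: computes, for every band, the zero-phase filtered
# signal on the windows [onset, onset + out_len) only, via one BLAS matrix
# multiply per band. Exactly equivalent to apply_filter_bank() followed by
# slicing (verified in the test suite).
#
# sig: channels x samples; onsets: 0-based window starts; returns list over
# bands of arrays [epoch, channel, time].
band_epoch_arrays <- function(sig, onsets, bands, out_len = 500L) {
  n_ch <- nrow(sig)
  n <- ncol(sig)
  L <- length(bands[[1]]$taps)
  for (b in bands) stopifnot(length(b$taps) == L)
  d <- (L - 1) / 2
  pad <- min(L, n - 1)
  # reflect-pad the whole session once (same convention as fir_filtfilt)
  sp <- cbind(sig[, seq_len(pad) + 1][, pad:1, drop = FALSE], sig,
              sig[, n - seq_len(pad), drop = FALSE])
  m <- out_len + L - 1
  # absolute 1-based start of each segment in the padded signal
  seg_start <- onsets + 1 + pad - d
  if (any(seg_start < 1) || any(seg_start + m - 1 > ncol(sp))) {
    stop("epoch window (plus filter context) outside the recorded session")
  }
  idx <- outer(seq_len(m) - 1L, seg_start, "+")     # m x E
  E <- length(onsets)
  block <- sp[, as.vector(idx), drop = FALSE]       # n_ch x (m*E)
  seg <- matrix(aperm(array(block, c(n_ch, m, E)), c(2, 1, 3)), m, n_ch * E)
  lapply(bands, function(b) {
    A <- toeplitz_filter_operator(b$taps, out_len)
    out <- A %*% seg                                # out_len x (n_ch*E)
    aperm(array(out, c(out_len, n_ch, E)), c(3, 2, 1))
  })
}
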