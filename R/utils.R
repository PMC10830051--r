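#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor fft median nextn quantile rbinom rnorm rpois runif
#'   var predict setNames
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage identifiers used to expand one global seed into independent substreams.
.STAGES <- c(
  schedule = 1L, behaviour = 2L, sources = 3L, background = 4L,
  noise = 5L, artifacts = 6L, resting = 7L, ica = 8L, cv = 9L,
  bootstrap = 10L, misc = 11L, topos = 12L
)

#' Derive a deterministic substream seed
#'
#' One global seed is expanded into independent per-stage (and per-participant)
#' substreams so that, e.g., regenerating behaviour does not perturb the sensor
#' noise stream. Purely arithmetic; result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed integer global seed.
#' @param stage one of `"schedule"`, `"behaviour"`, `"sources"`, `"background"`,
#'   `"noise"`, `"artifacts"`, `"resting"`, `"ica"`, `"cv"`, `"bootstrap"`,
#'   `"misc"`, `"topos"`.
#' @param participant integer participant index (0 for cohort-level streams).
#' @return integer seed for `set.seed()`.
#' @export
substream_seed <- function(seed, stage, participant = 0L) {
  if (!stage %in% names(.STAGES)) {
    stop("unknown substream stage: ", stage)
  }
  s <- (as.double(seed) %% 65521) * 32749 +
    as.double(participant) * 2053 + as.double(.STAGES[[stage]]) * 97
  as.integer(s %% 2147483646)
}

stopifnot_finite <- function(x, what = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

#' Standard 32-channel 10/20 montage labels
#'
#' Channel names of a typical 32-electrode actiCAP-style layout. For other
#' channel counts the first `n` names are used (padded with `ChNN` beyond 32).
#'
#' @param n number of channels.
#' @return character vector of length `n`.
#' @export
montage_labels <- function(n = 32L) {
  base <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10"
  )
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("Ch%02d", seq_len(n - length(base)) + length(base)))
}

# Population (n-denominator) standard deviation.
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

zscore_pop <- function(x) {
  s <- sd_pop(x)
  if (s == 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

unit_norm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

# |cosine| similarity between two vectors (sign-invariant topography match).
abs_cosine <- function(a, b) {
  abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
}
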