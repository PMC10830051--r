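# Reaction-time label handling: log transform, per-angle standardization with
# training-set statistics, MAD-based outlier removal, and inversion of
# predictions back to milliseconds.

#' Fit the per-angle label scaler on training reaction times
#'
#' Computes, per angular disparity, the mean and population standard deviation
#' (n denominator) of the log reaction times. Hold-out and validation labels
#' are standardized with these training statistics to avoid leakage.
#'
#' @param rt_ms training reaction times in ms.
#' @param angles angular disparity of each training epoch.
#' @return a `label_scaler`: data.frame with `angle`, `mean_log`, `sd_log`.
#' @export
fit_label_scaler <- function(rt_ms, angles) {
  stopifnot(length(rt_ms) == length(angles))
  ua <- sort(unique(angles))
  rows <- lapply(ua, function(a) {
    x <- log(rt_ms[angles == a])
    if (length(x) < 2) {
      stop("angle ", a, " has fewer than 2 training epochs")
    }
    s <- sd_pop(x)
    if (s == 0) stop("zero variance of log RT at angle ", a)
    data.frame(angle = a, mean_log = mean(x), sd_log = s)
  })
  structure(do.call(rbind, rows), class = c("label_scaler", "data.frame"))
}

scaler_row <- function(scaler, angles) {
  i <- match(angles, scaler$angle)
  if (anyNA(i)) {
    stop("angle(s) not covered by the label scaler: ",
         paste(unique(angles[is.na(i)]), collapse = ", "))
  }
  i
}

#' Standardize reaction times with a fitted label scaler
#'
#' `z = (log(RT) - mean_a) / sd_a` using the scaler's per-angle training
#' statistics.
#'
#' @param rt_ms reaction times in ms.
#' @param angles angular disparity per epoch.
#' @param scaler a [fit_label_scaler()] result.
#' @return numeric vector of standardized log reaction times.
#' @export
standardize_labels <- function(rt_ms, angles, scaler) {
  i <- scaler_row(scaler, angles)
  (log(rt_ms) - scaler$mean_log[i]) / scaler$sd_log[i]
}

#' Invert standardized predictions back to milliseconds
#'
#' `RT = exp(z * sd_a + mean_a)`; exact inverse of [standardize_labels()].
#'
#' @param z standardized log reaction times (e.g. model predictions).
#' @inheritParams standardize_labels
#' @return reaction times in ms.
#' @export
invert_labels <- function(z, angles, scaler) {
  i <- scaler_row(scaler, angles)
  exp(z * scaler$sd_log[i] + scaler$mean_log[i])
}

#' Training-set outlier mask by the per-angle 2.5 x MAD rule
#'
#' On log reaction times, per angle: an epoch is removed when its absolute
#' deviation from the angle's median exceeds `threshold` times the unscaled
#' MAD (`median(|x - median|)`, no consistency factor). A degenerate angle
#' group with MAD = 0 removes nothing. Never applied to hold-out data.
#'
#' @param rt_ms training reaction times in ms.
#' @param angles angular disparity per training epoch.
#' @param threshold MAD multiplier (2.5 by default).
#' @return logical vector, `TRUE` for retained epochs. If the rule would
#'   remove more than half of an angle group a warning is emitted (the mask is
#'   still returned).
#' @export
mad_outlier_mask <- function(rt_ms, angles, threshold = 2.5) {
  x <- log(rt_ms)
  keep <- rep(TRUE, length(x))
  for (a in unique(angles)) {
    idx <- which(angles == a)
    med <- median(x[idx])
    m <- median(abs(x[idx] - med))
    if (m == 0) next
    out <- abs(x[idx] - med) > threshold * m
    if (sum(out) > length(idx) / 2) {
      warning("MAD rule would remove more than half of angle group ", a)
    }
    keep[idx[out]] <- FALSE
  }
  keep
}
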