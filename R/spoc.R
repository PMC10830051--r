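# SPoC (Source Power Comodulation): supervised spatial filtering that finds
# the channel-space projection whose per-epoch band power maximally covaries
# with a continuous label, via the generalized eigenproblem
#   Cz w = lambda C w
# on the label-weighted average epoch covariance Cz and the grand-average C.

#' Per-epoch channel covariances and their (label-weighted) averages
#'
#' Channels are mean-centered within each epoch; `C_e = X_e X_e' / (T - 1)`.
#' The label weights are z-scored (population SD) across epochs before
#' averaging, so `Cz = mean_e(z_e C_e)`.
#'
#' @param epochs_band numeric array `[epoch, channel, time]` for one band.
#' @param z numeric label per epoch (standardized log reaction times).
#' @return a `covariance_set`: `per_epoch` (list of channel x channel
#'   matrices), `C` (grand mean), `Cz` (label-weighted mean), `z` (the
#'   z-scored labels used).
#' @export
epoch_covariances <- function(epochs_band, z) {
  stopifnot(length(dim(epochs_band)) == 3, dim(epochs_band)[1] == length(z))
  stopifnot_finite(epochs_band, "epoch data")
  stopifnot_finite(z, "labels")
  E <- dim(epochs_band)[1]
  Tn <- dim(epochs_band)[3]
  zs <- zscore_pop(z)
  per <- lapply(seq_len(E), function(e) {
    X <- epochs_band[e, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    X <- X - rowMeans(X)
    X %*% t(X) / (Tn - 1)
  })
  C <- Reduce(`+`, per) / E
  Cz <- Reduce(`+`, Map(`*`, per, zs)) / E
  structure(list(per_epoch = per, C = C, Cz = (Cz + t(Cz)) / 2,
                 z = zs, n_time = Tn),
            class = "covariance_set")
}

#' Fit the SPoC spatial filter for one band
#'
#' Solves the generalized symmetric eigenproblem `Cz w = lambda C w` after
#' shrinkage-regularizing `C` and returns the eigenvector with the largest
#' absolute eigenvalue, normalized to `w' C w = 1`. For this filter the
#' empirical covariance between per-epoch power `w' C_e w` and the z-scored
#' label equals the eigenvalue, and no other unit-`C`-norm filter achieves a
#' larger absolute covariance. The forward-model pattern is sign-fixed so its
#' largest-magnitude entry is positive.
#'
#' @param cov a [epoch_covariances()] result.
#' @param shrinkage shrinkage weight `gamma` in
#'   `C <- (1 - gamma) C + gamma tr(C)/n I` for numerical invertibility.
#' @return a `spoc_filter`: `w` (filter), `eigenvalue`, `pattern`
#'   (forward model `C w / (w' C w)`), plus all eigenvalues for reference.
#' @export
fit_spoc <- function(cov, shrinkage = 1e-6) {
  stopifnot(inherits(cov, "covariance_set"))
  n <- nrow(cov$C)
  C <- (1 - shrinkage) * cov$C + shrinkage * (sum(diag(cov$C)) / n) * diag(n)
  U <- tryCatch(chol(C), error = function(e) {
    stop("grand-average covariance singular beyond regularization: ",
         conditionMessage(e))
  })
  M <- backsolve(U, t(backsolve(U, t(cov$Cz), transpose = TRUE)),
                 transpose = TRUE)
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  k <- which.max(abs(eg$values))
  v <- eg$vectors[, k]
  w <- backsolve(U, v)
  w <- w / sqrt(drop(t(w) %*% C %*% w))
  pattern <- compute_pattern(w, cov$C)
  if (pattern[which.max(abs(pattern))] < 0) {
    pattern <- -pattern
    w <- -w
  }
  structure(
    list(w = as.numeric(w), eigenvalue = eg$values[k],
         pattern = as.numeric(pattern), eigenvalues = eg$values),
    class = "spoc_filter"
  )
}

#' Forward-model pattern of a spatial filter
#'
#' `a = C w / (w' C w)`: the scalp topography that the filtered component
#' projects back to. `w` is first normalized to unit `C`-norm, which makes
#' the pattern invariant to positive rescaling of the filter.
#'
#' @param w spatial filter (channels).
#' @param C grand-average channel covariance.
#' @return numeric pattern vector.
#' @export
compute_pattern <- function(w, C) {
  w <- w / sqrt(drop(t(w) %*% C %*% w))
  cw <- C %*% w
  as.numeric(cw / drop(t(w) %*% cw))
}

#' Fit SPoC filters for every band of an epoch set
#'
#' @param epochs a cropped `epoch_set` (training epochs only).
#' @param z standardized log reaction-time labels, one per training epoch.
#' @param shrinkage passed to [fit_spoc()].
#' @return a `spatial_filter_set`: list with per-band `spoc_filter`s, band
#'   definitions and channel labels.
#' @export
fit_spoc_bank <- function(epochs, z, shrinkage = 1e-6) {
  stopifnot(inherits(epochs, "epoch_set"), epochs$cropped)
  filters <- lapply(epochs$data, function(arr) {
    fit_spoc(epoch_covariances(arr, z), shrinkage)
  })
  structure(
    list(filters = filters, bands = epochs$bands,
         channel_labels = epochs$channel_labels),
    class = "spatial_filter_set"
  )
}

#' Log-variance band-power features
#'
#' For each band and epoch: the log of the (sample) variance of the spatially
#' filtered epoch, `log(var(w_b' X_{b,e}))` - one column per band. Filters
#' must come from the training set when applied to validation or hold-out
#' epochs (no leakage).
#'
#' @param epochs a cropped `epoch_set`.
#' @param filter_set a [fit_spoc_bank()] result (or any `spatial_filter_set`).
#' @return numeric matrix, epochs x bands.
#' @export
extract_features <- function(epochs, filter_set) {
  stopifnot(inherits(epochs, "epoch_set"), epochs$cropped,
            inherits(filter_set, "spatial_filter_set"))
  if (length(epochs$data) != length(filter_set$filters)) {
    stop("band count mismatch between epochs (", length(epochs$data),
         ") and filters (", length(filter_set$filters), ")")
  }
  E <- dim(epochs$data[[1]])[1]
  out <- matrix(NA_real_, E, length(filter_set$filters))
  for (b in seq_along(filter_set$filters)) {
    w <- filter_set$filters[[b]]$w
    arr <- epochs$data[[b]]
    n_ch <- dim(arr)[2]
    Tn <- dim(arr)[3]
    if (n_ch != length(w)) stop("channel count mismatch in band ", b)
    # project all epochs at once: Y[t, e] = w' X_e[, t]
    Y <- matrix(drop(matrix(w, 1) %*% matrix(aperm(arr, c(2, 3, 1)), n_ch)),
                Tn, E)
    v <- colSums(sweep(Y, 2, colMeans(Y))^2) / (Tn - 1)
    out[, b] <- log(v)
  }
  colnames(out) <- vapply(filter_set$bands,
                          function(b) sprintf("band_%g", b$center %||% NA), "")
  out
}
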