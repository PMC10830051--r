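# Model interpretation: exact SHAP attribution for the linear ridge model,
# per-participant and group-level importance summaries, and cross-participant
# forward-model pattern averaging.

#' Exact SHAP values for a linear model
#'
#' Under the independent-features (interventional) value function the Shapley
#' value of feature b for epoch x is exactly
#' `phi_b = beta_b * (x_b - mean(background_b))` in standardized feature
#' space, with base value the mean model prediction over the training
#' background. Additivity `base + sum_b phi_b = prediction` holds to machine
#' precision.
#'
#' @param model a `ridge_model` with an attached `feature_scaler`.
#' @param X_holdout hold-out feature matrix (raw scale).
#' @param X_background training feature matrix (raw scale) used as background.
#' @return a `shap_matrix`: `phi` (epochs x bands), `base`, `prediction`.
#' @export
linear_shap <- function(model, X_holdout, X_background) {
  if (is.null(X_background) || nrow(as.matrix(X_background)) == 0) {
    stop("background feature matrix is empty")
  }
  Xh <- as.matrix(X_holdout)
  Xb <- as.matrix(X_background)
  if (!is.null(model$feature_scaler)) {
    Xh <- apply_feature_scaler(Xh, model$feature_scaler)
    Xb <- apply_feature_scaler(Xb, model$feature_scaler)
  }
  mu <- colMeans(Xb)
  phi <- sweep(Xh, 2, mu) %*% diag(model$beta, ncol(Xh))
  colnames(phi) <- colnames(X_holdout)
  base <- model$intercept + drop(mu %*% model$beta)
  structure(
    list(phi = phi, base = base,
         prediction = drop(base + rowSums(phi))),
    class = "shap_matrix"
  )
}

#' Group-level SHAP importance summary
#'
#' Per participant: the mean absolute SHAP value per band (global importance).
#' Across participants: the median and MAD (unscaled) of these means per
#' band, plus the 10 x 10 table of mean absolute pairwise differences
#' `mean_p |m_b - m_b'|` between band importances.
#'
#' @param shap_list list of `shap_matrix` objects (one per participant).
#' @return an `importance_summary`: `per_participant` (participants x bands),
#'   `group_median`, `group_mad`, `pairwise_diff`.
#' @export
summarize_importance <- function(shap_list) {
  stopifnot(length(shap_list) >= 1)
  per <- t(vapply(shap_list, function(s) colMeans(abs(s$phi)),
                  numeric(ncol(shap_list[[1]]$phi))))
  med <- apply(per, 2, median)
  madv <- apply(per, 2, function(x) median(abs(x - median(x))))
  p <- ncol(per)
  pd <- matrix(0, p, p, dimnames = list(colnames(per), colnames(per)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      pd[i, j] <- mean(abs(per[, i] - per[, j]))
    }
  }
  structure(
    list(per_participant = per, group_median = med, group_mad = madv,
         pairwise_diff = pd),
    class = "importance_summary"
  )
}

#' Average forward-model patterns across participants
#'
#' Per band: patterns are sign-indeterminate, so each participant's pattern
#' is flipped, if needed, to correlate positively with the running mean
#' before averaging; the result is normalized to unit Euclidean norm. The
#' pre-normalization mean norm is returned as a consistency diagnostic
#' (near 0 for unrelated patterns, near 1 for a shared topography).
#'
#' @param filter_sets list of `spatial_filter_set` objects sharing a montage.
#' @return list with `patterns` (bands x channels, unit rows) and
#'   `mean_norm` (per band, before renormalization).
#' @export
average_patterns <- function(filter_sets) {
  stopifnot(length(filter_sets) >= 1)
  labels <- filter_sets[[1]]$channel_labels
  for (fs in filter_sets) {
    if (!identical(fs$channel_labels, labels)) {
      stop("montage mismatch across participants")
    }
  }
  n_band <- length(filter_sets[[1]]$filters)
  n_ch <- length(labels)
  out <- matrix(NA_real_, n_band, n_ch)
  mean_norm <- numeric(n_band)
  for (b in seq_len(n_band)) {
    acc <- numeric(n_ch)
    k <- 0
    for (fs in filter_sets) {
      a <- fs$filters[[b]]$pattern
      if (k > 0 && sum(a * acc) < 0) a <- -a
      acc <- acc + a
      k <- k + 1
    }
    m <- acc / k
    mean_norm[b] <- sqrt(sum(m^2))
    out[b, ] <- unit_norm(m)
  }
  colnames(out) <- labels
  list(patterns = out, mean_norm = mean_norm)
}
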