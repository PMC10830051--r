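# Evaluation designs: intra-individual EEG model vs the RT baseline,
# inter-individual transfer with pre-processor (bundle) swapping, and the
# bootstrap paired test.

#' Intra-individual evaluation of one participant
#'
#' The EEG model extracts hold-out features with the participant's own
#' training bundle and predicts; its MAE is compared with the RT baseline
#' that predicts the training-set average standardized reaction time per
#' angle, i.e. 0, for every hold-out epoch. Millisecond-scale MAEs are
#' obtained by inverting predictions and labels through the label scaler.
#'
#' @param pfit a `participant_fit` from [fit_participant()].
#' @return list with `mae_eeg`, `mae_baseline` (z units), `mae_ms_eeg`,
#'   `mae_ms_baseline` (ms) and a per-angle MAE table.
#' @export
evaluate_intra <- function(pfit) {
  stopifnot(inherits(pfit, "participant_fit"))
  hz <- pfit$holdout$z
  if (length(hz) == 0) stop("empty hold-out set")
  pred <- predict(pfit$model, pfit$holdout$features)
  angles <- pfit$holdout$angles
  rt <- pfit$holdout$rt_ms
  pred_ms <- invert_labels(pred, angles, pfit$label_scaler)
  base_ms <- invert_labels(rep(0, length(hz)), angles, pfit$label_scaler)
  per_angle <- do.call(rbind, lapply(sort(unique(angles)), function(a) {
    i <- angles == a
    data.frame(angle = a, n = sum(i),
               mae_eeg = mae(pred[i], hz[i]),
               mae_baseline = mean(abs(hz[i])))
  }))
  list(
    mae_eeg = mae(pred, hz),
    mae_baseline = mean(abs(hz)),
    mae_ms_eeg = mae(pred_ms, rt),
    mae_ms_baseline = mae(base_ms, rt),
    per_angle = per_angle
  )
}

#' Inter-individual transfer evaluation
#'
#' Applies the train participant's ridge coefficients to the test
#' participant's hold-out epochs. Features (and labels) are extracted with
#' the chosen pre-processor bundle: the train participant's
#' (`bundle_source = "train"`, the default transfer design) or the test
#' participant's own (`"test"`, the swapped design).
#'
#' @param train_fit,test_fit `participant_fit` objects.
#' @param bundle_source `"train"` or `"test"`.
#' @return scalar MAE in standardized units.
#' @export
evaluate_inter <- function(train_fit, test_fit,
                           bundle_source = c("train", "test")) {
  bundle_source <- match.arg(bundle_source)
  src <- if (bundle_source == "train") train_fit else test_fit
  if (!identical(dim(test_fit$holdout$epochs$data[[1]])[2],
                 length(src$filters$filters[[1]]$w))) {
    stop("channel count mismatch between participants")
  }
  if (length(test_fit$holdout$epochs$data) != length(src$filters$filters)) {
    stop("band count mismatch between participants")
  }
  feats <- extract_features(test_fit$holdout$epochs, src$filters)
  z <- standardize_labels(test_fit$holdout$rt_ms, test_fit$holdout$angles,
                          src$label_scaler)
  Xs <- apply_feature_scaler(feats, src$feature_scaler)
  pred <- drop(train_fit$model$intercept + Xs %*% train_fit$model$beta)
  mae(pred, z)
}

#' Full inter-individual MAE matrix for a cohort
#'
#' @param fits list of `participant_fit` objects.
#' @param bundle_source `"train"` or `"test"` (see [evaluate_inter()]).
#' @return square matrix; entry (i, j) is the MAE of participant i's model on
#'   participant j's hold-out set. The diagonal equals the intra-individual
#'   EEG MAEs.
#' @export
inter_mae_matrix <- function(fits, bundle_source = "train") {
  n <- length(fits)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- evaluate_inter(fits[[i]], fits[[j]], bundle_source)
    }
  }
  M
}

#' Bootstrap paired test
#'
#' Percentile bootstrap of the mean paired difference `d = a - b`:
#' participants are resampled with replacement `iterations` times; the 95%
#' CI is the 2.5/97.5 percentile interval and the two-sided p-value is
#' `2 * min(#{mean d* <= 0} + 1, #{mean d* >= 0} + 1) / (iterations + 1)`.
#'
#' @param a,b paired per-participant metric vectors (length >= 5).
#' @param iterations bootstrap iterations (9999 by default).
#' @param seed integer seed.
#' @return a `bootstrap_result`: `mean_diff`, `ci` (2.5/97.5 percentiles),
#'   `p`, `iterations`, `seed`.
#' @export
bootstrap_paired_test <- function(a, b, iterations = 9999, seed = 1L) {
  if (length(a) != length(b)) stop("length mismatch between paired vectors")
  n <- length(a)
  if (n < 5) stop("need at least 5 pairs")
  d <- a - b
  set.seed(seed)
  idx <- matrix(sample.int(n, n * iterations, replace = TRUE), iterations, n)
  means <- rowMeans(matrix(d[idx], iterations, n))
  p <- 2 * min(sum(means <= 0) + 1, sum(means >= 0) + 1) / (iterations + 1)
  structure(
    list(mean_diff = mean(d),
         ci = unname(quantile(means, c(0.025, 0.975), type = 7)),
         p = min(p, 1), iterations = iterations, seed = seed,
         boot_means = NULL),
    class = "bootstrap_result"
  )
}
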