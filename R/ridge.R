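# Closed-form ridge regression on the ten band-power features, with the
# chronological three-window sliding cross-validation used to tune the
# penalty lambda.

#' Fit the per-feature standardization scaler
#'
#' Training mean and population SD per feature column; features are
#' standardized before ridge fitting so a single lambda grid is meaningful
#' across participants.
#'
#' @param X feature matrix (epochs x features).
#' @return a `feature_scaler` with `mean` and `sd` vectors.
#' @export
fit_feature_scaler <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2, sd_pop)
  if (any(s <= 0)) stop("feature with zero variance; cannot standardize")
  structure(list(mean = m, sd = s), class = "feature_scaler")
}

#' @rdname fit_feature_scaler
#' @param scaler a `feature_scaler`.
#' @return `apply_feature_scaler`: the standardized matrix.
#' @export
apply_feature_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$mean), 2, scaler$sd, `/`)
}

#' Closed-form ridge regression
#'
#' Minimizes `sum_e (y_e - b0 - x_e' beta)^2 + lambda ||beta||^2` with an
#' unpenalized intercept: `beta = (X'X + lambda I)^-1 X' (y - ybar)`,
#' `b0 = ybar`. `X` must already be standardized (see
#' [fit_feature_scaler()]); attach the scaler so [predict()] can standardize
#' new data.
#'
#' @param X standardized feature matrix (n x p), n >= 2.
#' @param y numeric response (standardized log reaction times).
#' @param lambda ridge penalty, > 0.
#' @param feature_scaler optional `feature_scaler` to attach.
#' @param label_scaler optional `label_scaler` to attach.
#' @return a `ridge_model` with `beta`, `intercept`, `lambda` and the
#'   attached scalers.
#' @export
fit_ridge <- function(X, y, lambda, feature_scaler = NULL, label_scaler = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  if (lambda <= 0) stop("lambda must be > 0")
  p <- ncol(X)
  yc <- y - mean(y)
  beta <- solve(crossprod(X) + lambda * diag(p), crossprod(X, yc))
  structure(
    list(beta = as.numeric(beta), intercept = mean(y), lambda = lambda,
         feature_scaler = feature_scaler, label_scaler = label_scaler),
    class = "ridge_model"
  )
}

#' Predict from a ridge model
#'
#' @param object a `ridge_model`.
#' @param newdata feature matrix; standardized with the attached
#'   `feature_scaler` when present (otherwise assumed already standardized).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$beta)) {
    stop("feature count mismatch: model has ", length(object$beta),
         ", data has ", ncol(X))
  }
  if (!is.null(object$feature_scaler)) {
    X <- apply_feature_scaler(X, object$feature_scaler)
  }
  drop(object$intercept + X %*% object$beta)
}

#' Mean absolute error
#'
#' @param pred predictions.
#' @param y observed values.
#' @return scalar `mean(|pred - y|)`.
#' @export
mae <- function(pred, y) {
  stopifnot(length(pred) == length(y))
  mean(abs(pred - y))
}

#' Chronological three-window sliding CV split
#'
#' The training set is split into three equal-length overlapping windows
#' (length `floor(n / 1.9)`, stride `floor(0.45 L)`, starts 0, S, 2S). Within
#' each window the initial 55% of epochs train and the remaining 45% validate;
#' validation sets are pairwise disjoint and chronological, and the last
#' window's validation end is anchored to `n` (absorbing the rounding
#' remainder).
#'
#' @param n_train number of chronologically ordered training epochs (>= 20).
#' @return list of 3 windows, each with 1-based `train` and `validation`
#'   index vectors.
#' @export
make_windows <- function(n_train) {
  if (n_train < 20) stop("need at least 20 training epochs for the sliding CV")
  # epsilon guards keep floor/ceiling exact where the real-valued expression
  # is an integer (e.g. 190 / 1.9)
  L <- floor(n_train / 1.9 + 1e-9)
  S <- floor(0.45 * L + 1e-9)
  tr <- ceiling(0.55 * L - 1e-9)
  lapply(0:2, function(i) {
    start <- i * S
    val_end <- if (i == 2) n_train else start + L
    if (start + tr >= val_end) stop("empty validation set in window ", i + 1)
    list(train = (start + 1):(start + tr),
         validation = (start + tr + 1):val_end)
  })
}

#' Tune lambda by chronological sliding-window cross-validation
#'
#' For every lambda on an exponential grid between `10^-1` and `10^4`: fit on
#' each window's training part (re-fitting the feature scaler on that part),
#' measure the MAE on its validation part, and average across the three
#' windows. The lambda with the lowest mean MAE wins; ties go to the smaller
#' lambda.
#'
#' @param X training feature matrix (chronological order), extracted with
#'   training-set pre-processors.
#' @param y training labels.
#' @param grid lambda grid; default 25 log-spaced points on `[1e-1, 1e4]`.
#' @return a `cv_report`: `grid`, `mae` (windows x grid), `mean_mae`,
#'   `selected_lambda`, `selected_index`.
#' @export
cross_validate_lambda <- function(X, y, grid = lambda_grid()) {
  X <- as.matrix(X)
  wins <- make_windows(nrow(X))
  mae_mat <- matrix(NA_real_, length(wins), length(grid))
  for (wi in seq_along(wins)) {
    w <- wins[[wi]]
    sc <- fit_feature_scaler(X[w$train, , drop = FALSE])
    Xtr <- apply_feature_scaler(X[w$train, , drop = FALSE], sc)
    Xva <- apply_feature_scaler(X[w$validation, , drop = FALSE], sc)
    for (li in seq_along(grid)) {
      m <- fit_ridge(Xtr, y[w$train], grid[li])
      mae_mat[wi, li] <- mae(drop(m$intercept + Xva %*% m$beta), y[w$validation])
    }
  }
  mean_mae <- colMeans(mae_mat)
  sel <- which(mean_mae == min(mean_mae))[1]
  structure(
    list(grid = grid, mae = mae_mat, mean_mae = mean_mae,
         selected_lambda = grid[sel], selected_index = sel),
    class = "cv_report"
  )
}

#' Default exponential lambda grid
#'
#' @param n_points number of grid points.
#' @param low,high grid endpoints.
#' @return numeric vector of lambdas, log-spaced.
#' @export
lambda_grid <- function(n_points = 25, low = 1e-1, high = 1e4) {
  10^seq(log10(low), log10(high), length.out = n_points)
}
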