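# End-to-end orchestration: simulate -> preprocess -> fit -> evaluate ->
# interpret for a cohort of simulated participants.

#' Preprocess one participant's sessions into retained, cropped epochs
#'
#' ICA is fitted on the resting state (1 Hz high-passed copy), artifact
#' components are selected (config list first, automatic blink heuristic
#' otherwise) and removed from the raw task signal; the filter bank is then
#' applied and stimulus epochs are extracted, retained and cropped to their
#' initial 500 ms. For speed the band filtering is evaluated only on the
#' epoch windows via a banded-Toeplitz matrix product - numerically identical
#' to filtering the full session and slicing (asserted in the test suite).
#'
#' @param task task `raw_session`.
#' @param resting resting-state `raw_session`.
#' @param bands filter bank from [band_definitions()].
#' @param ica_reject explicit component list, `NULL` for automatic.
#' @param ica_seed seed for [fit_ica()].
#' @param min_rt_ms,crop_ms retention/crop parameters
#'   (see [filter_and_crop_epochs()]).
#' @return a cropped `epoch_set` (stimulus epochs only) with
#'   `removal_counts`; the fitted `ica_decomposition` and the rejected
#'   component indices are attached as fields `ica` and `ica_rejected`.
#' @export
preprocess_session <- function(task, resting, bands = band_definitions(),
                               ica_reject = NULL, ica_seed = 1L,
                               min_rt_ms = 700, crop_ms = 500) {
  ica <- fit_ica(resting, seed = ica_seed)
  rejected <- select_artifact_components(ica, resting, reject = ica_reject)
  clean <- apply_ica_cleaning(task, ica, rejected)

  tr <- clean$trials
  meta_all <- data.frame(
    trial_index = tr$trial_index, phase = "stimulus",
    start = tr$stimulus_onset, end = tr$stimulus_end,
    angle = tr$angle, mirrored = tr$mirrored,
    reaction_time_ms = tr$reaction_time_ms,
    correct = tr$correct, timeout = tr$timeout
  )
  rule_incorrect <- !meta_all$correct | meta_all$timeout
  rule_short <- !rule_incorrect & meta_all$reaction_time_ms < min_rt_ms
  keep <- !(rule_incorrect | rule_short)
  counts <- c(total = 2L * nrow(tr), fixation = nrow(tr),
              incorrect_or_missing = sum(rule_incorrect),
              too_early = sum(rule_short), retained = sum(keep))
  meta <- meta_all[keep, , drop = FALSE]
  rownames(meta) <- NULL
  len <- as.integer(round(crop_ms * clean$sampling_rate / 1000))
  data <- band_epoch_arrays(clean$signal, meta$start, bands, out_len = len)
  structure(
    list(data = data, meta = meta, bands = bands,
         sampling_rate = clean$sampling_rate,
         channel_labels = clean$channel_labels, cropped = TRUE,
         removal_counts = counts, ica = ica, ica_rejected = rejected),
    class = "epoch_set"
  )
}

#' Chronological train/hold-out split of a cropped epoch set
#'
#' @param epochs cropped `epoch_set`.
#' @param train_fraction fraction of epochs (chronological prefix) used for
#'   training; the split index is `floor(train_fraction * n)`.
#' @return list with `train` and `holdout` epoch sets.
#' @export
split_epochs <- function(epochs, train_fraction = 0.75) {
  stopifnot(inherits(epochs, "epoch_set"), epochs$cropped)
  n <- nrow(epochs$meta)
  n_tr <- floor(train_fraction * n)
  if (n_tr < 1 || n_tr >= n) stop("degenerate train/hold-out split")
  subset_es <- function(idx) {
    out <- epochs
    out$data <- lapply(epochs$data, function(a) a[idx, , , drop = FALSE])
    out$meta <- epochs$meta[idx, , drop = FALSE]
    rownames(out$meta) <- NULL
    out
  }
  list(train = subset_es(seq_len(n_tr)),
       holdout = subset_es((n_tr + 1):n))
}

#' Fit the full person-specific model for one participant
#'
#' Order of operations on the training prefix: log-RT MAD outlier removal
#' (training only), label-scaler fit on the retained epochs, SPoC filter fit
#' per band, feature extraction, feature-scaler fit, lambda tuning by
#' chronological sliding-window CV, final ridge fit on all retained training
#' epochs. Hold-out epochs are standardized and projected exclusively with
#' these training-set pre-processors.
#'
#' @param epochs cropped `epoch_set` for the participant.
#' @param train_fraction chronological train share (0.75).
#' @param grid lambda grid (see [lambda_grid()]).
#' @param mad_threshold multiplier of the outlier rule.
#' @param shrinkage SPoC covariance shrinkage.
#' @param id participant identifier.
#' @return a `participant_fit` carrying the pre-processor bundle (label
#'   scaler, spatial filters, feature scaler), the ridge model, the CV
#'   report, training features and the hold-out epochs/labels.
#' @export
fit_participant <- function(epochs, train_fraction = 0.75,
                            grid = lambda_grid(), mad_threshold = 2.5,
                            shrinkage = 1e-6, id = 1L) {
  sp <- split_epochs(epochs, train_fraction)
  train <- sp$train
  holdout <- sp$holdout

  keep <- mad_outlier_mask(train$meta$reaction_time_ms, train$meta$angle,
                           mad_threshold)
  train$data <- lapply(train$data, function(a) a[keep, , , drop = FALSE])
  train$meta <- train$meta[keep, , drop = FALSE]

  label_scaler <- fit_label_scaler(train$meta$reaction_time_ms,
                                   train$meta$angle)
  z_train <- standardize_labels(train$meta$reaction_time_ms,
                                train$meta$angle, label_scaler)
  filters <- fit_spoc_bank(train, z_train, shrinkage)
  X_train <- extract_features(train, filters)
  cv <- cross_validate_lambda(X_train, z_train, grid)
  feature_scaler <- fit_feature_scaler(X_train)
  model <- fit_ridge(apply_feature_scaler(X_train, feature_scaler), z_train,
                     cv$selected_lambda, feature_scaler, label_scaler)

  z_hold <- standardize_labels(holdout$meta$reaction_time_ms,
                               holdout$meta$angle, label_scaler)
  X_hold <- extract_features(holdout, filters)
  structure(
    list(id = id, label_scaler = label_scaler, filters = filters,
         feature_scaler = feature_scaler, model = model, cv = cv,
         train = list(features = X_train, z = z_train,
                      angles = train$meta$angle,
                      rt_ms = train$meta$reaction_time_ms,
                      n_before_outlier_removal = length(keep),
                      n = sum(keep)),
         holdout = list(epochs = holdout, features = X_hold, z = z_hold,
                        angles = holdout$meta$angle,
                        rt_ms = holdout$meta$reaction_time_ms),
         removal_counts = epochs$removal_counts),
    class = "participant_fit"
  )
}

#' Validated run configuration for a full cohort analysis
#'
#' @param x a named list or the path of a YAML file with (subsets of) keys:
#'   `cohort_size`, `seed`, `out_dir`, `sim` (arguments of [sim_config()]),
#'   `preprocess` (`band_centers`, `ica_reject`, `min_rt_ms`, `crop_ms`),
#'   `cv` (`grid_size`), `evaluation` (`bootstrap_iterations`),
#'   `shared_topographies` (draw one set of source topographies for the whole
#'   cohort). Unknown keys are rejected.
#' @return a `run_config` list with defaults filled in.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  known <- c("cohort_size", "seed", "out_dir", "sim", "preprocess", "cv",
             "evaluation", "shared_topographies")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  sub_known <- list(
    preprocess = c("band_centers", "ica_reject", "min_rt_ms", "crop_ms"),
    cv = c("grid_size"), evaluation = c("bootstrap_iterations")
  )
  for (s in names(sub_known)) {
    bad <- setdiff(names(x[[s]]), sub_known[[s]])
    if (length(bad) > 0) {
      stop("unknown ", s, " key(s): ", paste(bad, collapse = ", "))
    }
  }
  cfg <- list(
    cohort_size = x$cohort_size %||% 20L,
    seed = x$seed %||% 1L,
    out_dir = x$out_dir %||% NULL,
    sim = x$sim %||% list(),
    preprocess = list(
      band_centers = x$preprocess$band_centers %||% seq(2, 38, by = 4),
      ica_reject = x$preprocess$ica_reject %||% NULL,
      min_rt_ms = x$preprocess$min_rt_ms %||% 700,
      crop_ms = x$preprocess$crop_ms %||% 500
    ),
    cv = list(grid_size = x$cv$grid_size %||% 25L),
    evaluation = list(bootstrap_iterations = x$evaluation$bootstrap_iterations %||% 9999L),
    shared_topographies = isTRUE(x$shared_topographies)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Run the full cohort pipeline
#'
#' Simulates `cohort_size` participants, preprocesses and fits each, then
#' evaluates intra- and inter-individual performance (both bundle sources),
#' runs the bootstrap paired tests, and summarizes SHAP importance and
#' average SPoC patterns. When `config$out_dir` is set, per-participant model
#' bundles (JSON), tidy TSV reports and a JSON summary are written.
#'
#' @param config a [run_config()] (or list coerced through it).
#' @param progress print per-stage log lines.
#' @return a `cohort_report` list; see fields `intra`, `inter`, `bootstrap`,
#'   `importance`, `patterns`, `summary`.
#' @export
run_full <- function(config = run_config(), progress = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  n <- config$cohort_size
  bands <- band_definitions(config$preprocess$band_centers)
  grid <- lambda_grid(config$cv$grid_size)
  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  base_cfg <- do.call(sim_config, sim_args)
  if (config$shared_topographies) {
    shared <- planted_topographies(base_cfg, participant = 0L)
    base_cfg$source_specs <- Map(function(sp, topo) {
      sp$topography <- topo
      sp
    }, base_cfg$source_specs, shared)
  }

  fits <- vector("list", n)
  for (p in seq_len(n)) {
    stage <- "simulate"
    res <- tryCatch({
      part <- simulate_participant(base_cfg, participant = p)
      stage <- "preprocess"
      ep <- preprocess_session(
        part$task, part$resting, bands,
        ica_reject = config$preprocess$ica_reject,
        ica_seed = substream_seed(config$seed, "ica", p),
        min_rt_ms = config$preprocess$min_rt_ms,
        crop_ms = config$preprocess$crop_ms
      )
      if (progress) {
        message(sprintf(
          "participant %d | seed %d | removed: %d incorrect/missing, %d too early | retained %d",
          p, substream_seed(config$seed, "misc", p),
          ep$removal_counts[["incorrect_or_missing"]],
          ep$removal_counts[["too_early"]], ep$removal_counts[["retained"]]))
      }
      stage <- "fit"
      fit_participant(ep, grid = grid, id = p)
    }, error = function(e) {
      stop("stage '", stage, "' failed for participant ", p, ": ",
           conditionMessage(e))
    })
    fits[[p]] <- res
  }

  intra <- lapply(fits, evaluate_intra)
  intra_tab <- data.frame(
    participant = seq_len(n),
    mae_eeg = vapply(intra, `[[`, 0, "mae_eeg"),
    mae_baseline = vapply(intra, `[[`, 0, "mae_baseline"),
    mae_ms_eeg = vapply(intra, `[[`, 0, "mae_ms_eeg"),
    mae_ms_baseline = vapply(intra, `[[`, 0, "mae_ms_baseline"),
    selected_lambda = vapply(fits, function(f) f$cv$selected_lambda, 0)
  )

  M_train <- inter_mae_matrix(fits, "train")
  M_test <- inter_mae_matrix(fits, "test")
  off_mean <- function(M, i) mean(M[i, -i])
  inter_tab <- data.frame(
    participant = seq_len(n),
    inter_mae_train_bundle = vapply(seq_len(n), function(i) off_mean(M_train, i), 0),
    inter_mae_test_bundle = vapply(seq_len(n), function(i) off_mean(M_test, i), 0)
  )

  bi <- config$evaluation$bootstrap_iterations
  boot <- if (n < 5) NULL else list(
    eeg_vs_baseline = bootstrap_paired_test(
      intra_tab$mae_eeg, intra_tab$mae_baseline, bi,
      substream_seed(config$seed, "bootstrap", 1L)),
    intra_vs_inter = bootstrap_paired_test(
      intra_tab$mae_eeg, inter_tab$inter_mae_train_bundle, bi,
      substream_seed(config$seed, "bootstrap", 2L)),
    test_vs_train_bundle = bootstrap_paired_test(
      inter_tab$inter_mae_test_bundle, inter_tab$inter_mae_train_bundle, bi,
      substream_seed(config$seed, "bootstrap", 3L))
  )

  shap_list <- lapply(fits, function(f) {
    linear_shap(f$model, f$holdout$features, f$train$features)
  })
  importance <- summarize_importance(shap_list)
  patterns <- average_patterns(lapply(fits, `[[`, "filters"))

  report <- structure(
    list(config = config, fits = fits, intra = intra_tab, inter = inter_tab,
         inter_matrix_train = M_train, inter_matrix_test = M_test,
         bootstrap = boot, importance = importance, patterns = patterns,
         per_angle = lapply(intra, `[[`, "per_angle"),
         summary = list(
           n_participants = n,
           mean_mae_eeg = mean(intra_tab$mae_eeg),
           mean_mae_baseline = mean(intra_tab$mae_baseline),
           mean_mae_ms_eeg = mean(intra_tab$mae_ms_eeg),
           mean_mae_ms_baseline = mean(intra_tab$mae_ms_baseline),
           mean_inter_mae_train_bundle = mean(inter_tab$inter_mae_train_bundle),
           mean_inter_mae_test_bundle = mean(inter_tab$inter_mae_test_bundle),
           median_lambda = median(intra_tab$selected_lambda),
           p_eeg_vs_baseline = boot$eeg_vs_baseline$p %||% NA,
           p_intra_vs_inter = boot$intra_vs_inter$p %||% NA,
           p_test_vs_train_bundle = boot$test_vs_train_bundle$p %||% NA
         )),
    class = "cohort_report"
  )
  if (!is.null(config$out_dir)) write_cohort_report(report, config$out_dir)
  report
}

#' Write a cohort report to disk
#'
#' Tidy TSV tables (`intra.tsv`, `inter.tsv`, `importance.tsv`,
#' `patterns.tsv`, `per_angle.tsv`), a JSON `summary.json` and one JSON model
#' bundle per participant under `models/`.
#'
#' @param report a `cohort_report`.
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_cohort_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) {
    write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(report$intra, "intra.tsv")
  tsv(report$inter, "inter.tsv")
  imp <- report$importance
  imp_tab <- do.call(rbind, lapply(seq_len(nrow(imp$per_participant)),
    function(i) data.frame(participant = i,
                           band = colnames(imp$per_participant),
                           mean_abs_shap = imp$per_participant[i, ])))
  tsv(imp_tab, "importance.tsv")
  pat <- as.data.frame(report$patterns$patterns)
  pat <- cbind(band = seq_len(nrow(pat)), pat)
  tsv(pat, "patterns.tsv")
  pa <- do.call(rbind, Map(function(tab, p) cbind(participant = p, tab),
                           report$per_angle, seq_along(report$per_angle)))
  tsv(pa, "per_angle.tsv")
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  mdir <- file.path(out_dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (f in report$fits) {
    bundle <- list(
      id = f$id,
      beta = f$model$beta, intercept = f$model$intercept,
      lambda = f$model$lambda,
      feature_scaler = f$feature_scaler[c("mean", "sd")],
      label_scaler = as.data.frame(f$label_scaler),
      spoc = lapply(f$filters$filters, function(fl) {
        list(w = fl$w, eigenvalue = fl$eigenvalue, pattern = fl$pattern)
      }),
      channel_labels = f$filters$channel_labels
    )
    jsonlite::write_json(bundle,
                         file.path(mdir, sprintf("participant-%02d.json", f$id)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}
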