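#' Model configuration
#'
#' Hyperparameter grid and cross-validation settings for the boosted-tree
#' recovery-score regressor. Tuning uses 5-fold cross-validation on the
#' training set, assessment 10-fold; folds are grouped by patient (all of
#' a patient's days in one fold) so no patient leaks across folds. Early
#' stopping monitors a held-out tenth of the training patients.
#'
#' @param grid named list of hyperparameter vectors (`eta`, `max_depth`,
#'   `nrounds`, `subsample`); the search visits their full crossing in
#'   declared order.
#' @param early_stopping_rounds boosting rounds without improvement before
#'   stopping; `0` disables early stopping.
#' @param es_frac fraction of training patients held out for early
#'   stopping.
#' @param cv_folds_tuning,cv_folds_assess fold counts.
#' @param elimination_alpha significance level of the Friedman/Nemenyi
#'   feature-elimination stop rule.
#' @param group_by_patient keep all of a patient's days in one fold
#'   (recommended); `FALSE` folds on raw rows.
#' @param seed integer seed for fold assignment and boosting.
#' @return a `model_config` list.
#' @export
model_config <- function(grid = list(eta = c(0.1, 0.3),
                                     max_depth = c(2L, 3L, 4L),
                                     nrounds = 300L,
                                     subsample = 0.9),
                         early_stopping_rounds = 50L,
                         es_frac = 0.1,
                         cv_folds_tuning = 5L,
                         cv_folds_assess = 10L,
                         elimination_alpha = 0.05,
                         group_by_patient = TRUE,
                         seed = 1L) {
  if (elimination_alpha <= 0 || elimination_alpha >= 1) {
    stop("config error: elimination_alpha must be in (0,1)", call. = FALSE)
  }
  if (cv_folds_tuning < 2L || cv_folds_assess < 2L) {
    stop("config error: fold counts must be >= 2", call. = FALSE)
  }
  structure(list(grid = grid, early_stopping_rounds = early_stopping_rounds,
                 es_frac = es_frac, cv_folds_tuning = cv_folds_tuning,
                 cv_folds_assess = cv_folds_assess,
                 elimination_alpha = elimination_alpha,
                 group_by_patient = group_by_patient,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Standardize feature columns
#'
#' Scales every feature to zero mean and unit variance. Parameters are
#' fitted on training data and reapplied to test data; missing entries
#' stay missing; zero-variance features pass through unchanged (their
#' scale is treated as 1).
#'
#' @param frames feature frame (`patient_id`, `day`, feature columns).
#' @param params optional parameters from a previous fit (named list with
#'   `center` and `scale`); when supplied they are applied instead of
#'   refitted.
#' @return list with `frames` (standardized) and `params`.
#' @export
standardize <- function(frames, params = NULL) {
  feat_cols <- setdiff(names(frames), c("patient_id", "day"))
  if (is.null(params)) {
    center <- vapply(feat_cols, function(fc) {
      x <- frames[[fc]]; if (all(is.na(x))) 0 else mean(x, na.rm = TRUE)
    }, numeric(1))
    scale <- vapply(feat_cols, function(fc) {
      x <- frames[[fc]]
      s <- sqrt(pop_var(x))
      if (is.na(s) || s == 0) 1 else s
    }, numeric(1))
    params <- list(center = center, scale = scale)
  }
  for (fc in feat_cols) {
    frames[[fc]] <- (frames[[fc]] - params$center[[fc]]) / params$scale[[fc]]
  }
  list(frames = frames, params = params)
}

# grouped (or row-wise) fold assignment; returns integer fold id per row
make_folds <- function(frames, k, group_by_patient = TRUE, seed = 1L) {
  set.seed(seed)
  if (group_by_patient) {
    ids <- unique(frames$patient_id)
    if (k > length(ids)) {
      stop(sprintf("input error: k = %d exceeds the %d patients", k, length(ids)),
           call. = FALSE)
    }
    fold_of <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
    unname(fold_of[frames$patient_id])
  } else {
    if (k > nrow(frames)) stop("input error: k exceeds the number of rows",
                               call. = FALSE)
    sample(rep_len(seq_len(k), nrow(frames)))
  }
}

frame_matrix <- function(frames, features) {
  miss <- setdiff(features, names(frames))
  if (length(miss)) {
    stop("input error: unknown feature columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(frames[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# Fit one booster, optionally with an early-stopping holdout taken from a
# fraction of the training patients. Returns the xgb.Booster.
fit_booster <- function(frames, targets, hyperparams, features, config) {
  es_rounds <- config$early_stopping_rounds
  params <- list(objective = "reg:squarederror",
                 eta = hyperparams$eta,
                 max_depth = hyperparams$max_depth,
                 subsample = hyperparams$subsample,
                 nthread = 1, seed = config$seed)
  ids <- unique(frames$patient_id)
  n_hold <- floor(config$es_frac * length(ids))
  use_es <- es_rounds > 0 && n_hold >= 1 && length(ids) - n_hold >= 2
  if (use_es) {
    set.seed(config$seed)
    hold_ids <- sample(ids, n_hold)
    hold <- frames$patient_id %in% hold_ids
    dtrain <- xgboost::xgb.DMatrix(frame_matrix(frames[!hold, ], features),
                                   label = targets[!hold], missing = NA)
    dhold <- xgboost::xgb.DMatrix(frame_matrix(frames[hold, ], features),
                                  label = targets[hold], missing = NA)
    booster <- xgboost::xgb.train(params, dtrain, nrounds = hyperparams$nrounds,
                                  evals = list(holdout = dhold),
                                  early_stopping_rounds = es_rounds,
                                  verbose = 0)
  } else {
    dtrain <- xgboost::xgb.DMatrix(frame_matrix(frames, features),
                                   label = targets, missing = NA)
    booster <- xgboost::xgb.train(params, dtrain, nrounds = hyperparams$nrounds,
                                  verbose = 0)
  }
  booster
}

predict_booster <- function(booster, frames, features) {
  m <- frame_matrix(frames, features)
  stats::predict(booster, xgboost::xgb.DMatrix(m, missing = NA))
}

#' Tune hyperparameters by cross-validation
#'
#' Evaluates every grid point with k-fold cross-validation grouped by
#' patient and returns the point with the lowest mean validation MSE.
#' Ties keep the first point in grid order.
#'
#' @param frames standardized training feature frame.
#' @param targets numeric reference score per row of `frames`.
#' @param config a [model_config()].
#' @param features feature columns to use.
#' @return list: the winning hyperparameters plus `mean_mse` and the full
#'   `search` table.
#' @export
tune_hyperparameters <- function(frames, targets, config = model_config(),
                                 features = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(frames), c("patient_id", "day"))
  }
  grid <- do.call(expand.grid,
                  c(config$grid, list(KEEP.OUT.ATTRS = FALSE,
                                      stringsAsFactors = FALSE)))
  if (nrow(grid) == 0L) stop("config error: empty hyperparameter grid",
                             call. = FALSE)
  folds <- make_folds(frames, config$cv_folds_tuning,
                      config$group_by_patient, config$seed)
  mean_mse <- vapply(seq_len(nrow(grid)), function(g) {
    hp <- as.list(grid[g, , drop = FALSE])
    mse_g <- vapply(seq_len(config$cv_folds_tuning), function(f) {
      tr <- folds != f
      booster <- fit_booster(frames[tr, ], targets[tr], hp, features, config)
      pred <- predict_booster(booster, frames[!tr, ], features)
      mean((pred - targets[!tr])^2)
    }, numeric(1))
    mean(mse_g)
  }, numeric(1))
  best <- which.min(mean_mse)  # which.min takes the first on ties
  out <- as.list(grid[best, , drop = FALSE])
  out$mean_mse <- mean_mse[best]
  out$search <- cbind(grid, mean_mse = mean_mse)
  out
}

#' Cross-validated assessment
#'
#' Retrains the model with fixed hyperparameters under k-fold
#' cross-validation (folds grouped by patient) and reports per-fold
#' validation metrics.
#'
#' @inheritParams tune_hyperparameters
#' @param hyperparams list with `eta`, `max_depth`, `nrounds`,
#'   `subsample`.
#' @param k number of folds.
#' @return data.frame with one row per fold: `fold`, `mse`, `srcc`.
#' @export
cross_validate <- function(frames, targets, hyperparams,
                           k = 10L, config = model_config(), features = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(frames), c("patient_id", "day"))
  }
  folds <- make_folds(frames, k, config$group_by_patient, config$seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    booster <- fit_booster(frames[tr, ], targets[tr], hyperparams, features, config)
    pred <- predict_booster(booster, frames[!tr, ], features)
    obs <- targets[!tr]
    data.frame(fold = f, mse = mean((pred - obs)^2),
               srcc = suppressWarnings(stats::cor(pred, obs, method = "spearman")))
  })
  do.call(rbind, rows)
}

#' Train the final recovery-score model
#'
#' Fits a gradient-boosted tree regressor on all training patient-days.
#' Each day is an independent sample; the model never sees patient
#' identity or the day index. Missing feature values are handled natively
#' (rows follow the learned default direction at a split). Raw feature
#' frames are standardized internally and the fitted standardization
#' parameters travel with the model.
#'
#' @param frames raw (unstandardized) training feature frame.
#' @param targets reference recovery score per row.
#' @param hyperparams hyperparameter list, e.g. from
#'   [tune_hyperparameters()].
#' @param features feature columns to train on.
#' @param config a [model_config()].
#' @return a `recovery_model`: booster, standardization params, feature
#'   list, hyperparameters.
#' @export
train_final <- function(frames, targets, hyperparams, features = NULL,
                        config = model_config()) {
  if (is.null(features)) {
    features <- setdiff(names(frames), c("patient_id", "day"))
  }
  if (length(features) < 1L) stop("at least one feature is required",
                                  call. = FALSE)
  all_missing <- features[vapply(features,
                                 function(fc) all(is.na(frames[[fc]])),
                                 logical(1))]
  if (length(all_missing)) {
    warning("feature(s) entirely missing in training data: ",
            paste(all_missing, collapse = ", "), " (retained; native handling)")
  }
  std <- standardize(frames)
  booster <- fit_booster(std$frames, targets, hyperparams, features, config)
  structure(list(booster = booster, std_params = std$params,
                 features = features, hyperparams = hyperparams,
                 config = config),
            class = "recovery_model")
}

#' Predict daily recovery scores
#'
#' @param object a `recovery_model` from [train_final()].
#' @param frames raw feature frame with `patient_id` and `day` columns.
#' @param ... unused.
#' @return data.frame `patient_id`, `day`, `pred` (one score per
#'   patient-day in `frames`).
#' @export
predict.recovery_model <- function(object, frames, ...) {
  if (nrow(frames) == 0L) {
    return(data.frame(patient_id = character(0), day = integer(0),
                      pred = numeric(0)))
  }
  std <- standardize(frames, params = object$std_params)
  data.frame(patient_id = frames$patient_id, day = frames$day,
             pred = predict_booster(object$booster, std$frames, object$features),
             stringsAsFactors = FALSE)
}

#' Feature importance of a trained model
#'
#' @param model a `recovery_model`.
#' @return named numeric vector of total gain per feature (0 for features
#'   the booster never used), in decreasing order.
#' @export
model_importance <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  gain <- stats::setNames(rep(0, length(model$features)), model$features)
  if (!is.null(imp) && nrow(imp) > 0) gain[imp$Feature] <- imp$Gain
  sort(gain, decreasing = TRUE)
}

#' Evaluate predictions against reference profiles
#'
#' Mean squared error and Spearman rank correlation over all patient-days,
#' and the discharge error: the mean over patients of the absolute
#' difference between predicted and reference score on the discharge day.
#'
#' @param predictions data.frame `patient_id`, `day`, `pred`.
#' @param profiles named list of `recovery_profile`.
#' @param discharge_days named integer vector (patient id -> discharge
#'   day); defaults to each profile's `los`.
#' @return list `mse`, `srcc`, `discharge_error`, `pearson_r`, `n`.
#' @export
evaluate_predictions <- function(predictions, profiles, discharge_days = NULL) {
  ref <- profiles_frame(profiles)
  merged <- merge(predictions, ref, by = c("patient_id", "day"))
  merged <- merged[!is.na(merged$score) & !is.na(merged$pred), ]
  if (nrow(merged) == 0L) stop("input error: no overlapping patient-days",
                               call. = FALSE)
  if (is.null(discharge_days)) {
    discharge_days <- vapply(profiles, `[[`, integer(1), "los")
  }
  derr <- vapply(names(discharge_days), function(pid) {
    dd <- discharge_days[[pid]]
    row <- merged[merged$patient_id == pid & merged$day == dd, ]
    if (nrow(row) == 0L) return(NA_real_)
    abs(row$pred[1] - row$score[1])
  }, numeric(1))
  list(
    mse = mean((merged$pred - merged$score)^2),
    srcc = suppressWarnings(stats::cor(merged$pred, merged$score,
                                       method = "spearman")),
    discharge_error = mean(derr, na.rm = TRUE),
    pearson_r = suppressWarnings(stats::cor(merged$pred, merged$score)),
    n = nrow(merged)
  )
}
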