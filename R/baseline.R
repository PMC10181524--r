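#' Penalized-linear baseline regressor
#'
#' A ridge/lasso baseline behind the same predict interface as the
#' boosted-tree model, for sanity comparisons. Linear models have no
#' native missing-value routing, so missing standardized features are
#' imputed at 0 (the training mean).
#'
#' @param frames raw training feature frame.
#' @param targets reference score per row.
#' @param features feature columns.
#' @param alpha elastic-net mixing (0 ridge, 1 lasso).
#' @param lambda penalty; chosen by `glmnet::cv.glmnet` when `NULL`.
#' @return a `recovery_baseline` model usable with `predict`.
#' @export
train_baseline <- function(frames, targets, features = NULL, alpha = 0,
                           lambda = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(frames), c("patient_id", "day"))
  }
  std <- standardize(frames)
  x <- frame_matrix(std$frames, features)
  x[is.na(x)] <- 0
  if (is.null(lambda)) {
    cv <- glmnet::cv.glmnet(x, targets, alpha = alpha, nfolds = 5)
    lambda <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, targets, alpha = alpha, lambda = lambda)
  structure(list(fit = fit, std_params = std$params, features = features,
                 lambda = lambda),
            class = "recovery_baseline")
}

#' @export
predict.recovery_baseline <- function(object, frames, ...) {
  std <- standardize(frames, params = object$std_params)
  x <- frame_matrix(std$frames, object$features)
  x[is.na(x)] <- 0
  data.frame(patient_id = frames$patient_id, day = frames$day,
             pred = as.numeric(stats::predict(object$fit, newx = x)),
             stringsAsFactors = FALSE)
}
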