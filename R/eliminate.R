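#' Nemenyi post hoc test
#'
#' All-pairs comparison of k related samples (e.g. models measured on the
#' same cross-validation folds), following a Friedman test. Observations
#' are ranked within each block; the pairwise statistic is the difference
#' in mean ranks scaled by `sqrt(k(k+1)/(6n))`, referred to the
#' studentized range distribution.
#'
#' @param mat numeric matrix, one row per block (fold), one column per
#'   group (model).
#' @return symmetric matrix of pairwise p-values.
#' @export
nemenyi_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1, rank))
  mean_ranks <- colMeans(r)
  se <- sqrt(k * (k + 1) / (6 * n))
  p <- matrix(1, k, k, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      q <- abs(mean_ranks[i] - mean_ranks[j]) / se * sqrt(2)
      p[i, j] <- p[j, i] <- stats::ptukey(q, nmeans = k, df = Inf,
                                          lower.tail = FALSE)
    }
  }
  p
}

# Friedman omnibus p followed by Nemenyi p of the last column (candidate
# model) against the first (full model).
compare_to_full <- function(mat) {
  ftest <- stats::friedman.test(as.matrix(mat))
  nem <- nemenyi_test(mat)
  list(friedman_p = ftest$p.value, nemenyi_p = nem[1, ncol(mat)])
}

#' Backward feature elimination
#'
#' Iteratively removes the feature with the lowest importance (total gain)
#' and compares the reduced model's per-fold cross-validated MSE and SRCC
#' against the all-features model with a Friedman test followed by a
#' Nemenyi post hoc test. Elimination stops as soon as either metric
#' differs significantly from the full model at `config$elimination_alpha`,
#' and the last non-significantly-different feature set is returned. The
#' selection never returns an empty set.
#'
#' @param frames standardized training feature frame.
#' @param targets reference score per row.
#' @param hyperparams tuned hyperparameter list.
#' @param config a [model_config()].
#' @param features starting feature set (defaults to every feature
#'   column).
#' @return list: `selected` (character vector), `history` (per-step mean
#'   MSE/SRCC and test p-values), `full_cv` and `selected_cv` per-fold
#'   metric tables.
#' @export
backward_eliminate <- function(frames, targets, hyperparams,
                               config = model_config(), features = NULL) {
  if (is.null(features)) {
    features <- setdiff(names(frames), c("patient_id", "day"))
  }
  if (length(features) < 2L) stop("need at least 2 features to eliminate",
                                  call. = FALSE)
  k <- config$cv_folds_assess
  cv_for <- function(feats) {
    cross_validate(frames, targets, hyperparams, k = k, config = config,
                   features = feats)
  }
  full_cv <- cv_for(features)
  current <- features
  selected <- features
  selected_cv <- full_cv
  history <- list(data.frame(step = 0L, n_features = length(features),
                             dropped = NA_character_,
                             mean_mse = mean(full_cv$mse),
                             mean_srcc = mean(full_cv$srcc),
                             p_mse = NA_real_, p_srcc = NA_real_,
                             significant = FALSE, stringsAsFactors = FALSE))
  step <- 0L
  while (length(current) > 1L) {
    step <- step + 1L
    model <- train_final(frames, targets, hyperparams, features = current,
                         config = config)
    gain <- model_importance(model)
    # first feature (in current order) attaining the minimum gain
    drop <- current[which.min(gain[current])]
    candidate <- setdiff(current, drop)
    cand_cv <- cv_for(candidate)
    cmp_mse <- compare_to_full(cbind(full = full_cv$mse, reduced = cand_cv$mse))
    cmp_srcc <- compare_to_full(cbind(full = full_cv$srcc, reduced = cand_cv$srcc))
    sig <- function(cmp) {
      !is.na(cmp$friedman_p) && cmp$friedman_p < config$elimination_alpha &&
        cmp$nemenyi_p < config$elimination_alpha
    }
    significant <- sig(cmp_mse) || sig(cmp_srcc)
    history[[step + 1L]] <- data.frame(
      step = step, n_features = length(candidate), dropped = drop,
      mean_mse = mean(cand_cv$mse), mean_srcc = mean(cand_cv$srcc),
      p_mse = cmp_mse$nemenyi_p, p_srcc = cmp_srcc$nemenyi_p,
      significant = significant, stringsAsFactors = FALSE)
    if (significant) break
    current <- candidate
    selected <- candidate
    selected_cv <- cand_cv
  }
  list(selected = selected,
       history = do.call(rbind, history),
       full_cv = full_cv,
       selected_cv = selected_cv)
}
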