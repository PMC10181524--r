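# Train the daily recovery-score regressor: standardize on the training
# set, tune the boosted-tree hyperparameters with 5-fold CV, run backward
# feature elimination under the Friedman/Nemenyi stop rule, train the
# final model, and evaluate on the held-out test patients.

source("analysis/common.R")
stopifnot_exists("features.csv", "split.json", "cohort.json",
                 "feature_correlations.csv")

cohort <- read_cohort(path_in_results("cohort.json"))
dspec <- drop_spec(magnitude = unlist(study_config$drop$magnitude),
                   lead_days = unlist(study_config$drop$lead_days))
profiles <- build_reference_profiles(cohort, dspec,
                                     horizon = study_config$horizon)
split <- jsonlite::read_json(path_in_results("split.json"),
                             simplifyVector = TRUE)
frames <- read.csv(path_in_results("features.csv"),
                   stringsAsFactors = FALSE)

ref <- profiles_frame(profiles)
frames <- merge(frames, ref, by = c("patient_id", "day"))
frames <- frames[!is.na(frames$score), ]
frames <- frames[order(frames$patient_id, frames$day), ]
target <- frames$score
frames$score <- NULL

screen <- read.csv(path_in_results("feature_correlations.csv"),
                   stringsAsFactors = FALSE)
model_features <- head(screen$feature[!is.na(screen$pearson_r)],
                       study_config$screen_top_n)

train_rows <- frames$patient_id %in% split$train_ids
mod_cfg <- do.call(model_config,
                   utils::modifyList(list(seed = study_config$seed + 2L),
                                     study_config$model))
std <- standardize(frames[train_rows, ])

tuned <- tune_hyperparameters(std$frames, target[train_rows], mod_cfg,
                              features = model_features)
hyper <- tuned[c("eta", "max_depth", "nrounds", "subsample")]
cat("Tuned hyperparameters: eta", hyper$eta, ", max depth", hyper$max_depth,
    "(mean 5-fold CV MSE", signif(tuned$mean_mse, 3), ")\n")

elim <- backward_eliminate(std$frames, target[train_rows], hyper,
                           config = mod_cfg, features = model_features)
cat(sprintf("Backward elimination: %d -> %d features\n",
            length(model_features), length(elim$selected)))
print(elim$history, digits = 3)
write.csv(elim$history, path_in_results("elimination_history.csv"),
          row.names = FALSE)

model <- train_final(frames[train_rows, ], target[train_rows], hyper,
                     features = elim$selected, config = mod_cfg)
predictions <- predict(model, frames)
write.csv(predictions, path_in_results("predictions.csv"), row.names = FALSE)

test_metrics <- evaluate_predictions(
  predictions[!train_rows, ], profiles[split$test_ids])
train_metrics <- evaluate_predictions(
  predictions[train_rows, ], profiles[split$train_ids])
jsonlite::write_json(list(test = test_metrics, train = train_metrics,
                          hyperparams = hyper,
                          selected_features = elim$selected,
                          importance = as.list(model_importance(model))),
                     path_in_results("metrics.json"), auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("Test:  MSE %.4f | SRCC %.3f | discharge error %.4f | R %.3f\n",
            test_metrics$mse, test_metrics$srcc,
            test_metrics$discharge_error, test_metrics$pearson_r))
cat(sprintf("Train: MSE %.4f | SRCC %.3f | discharge error %.4f\n",
            train_metrics$mse, train_metrics$srcc,
            train_metrics$discharge_error))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  scatter <- merge(predictions[!train_rows, ], ref,
                   by = c("patient_id", "day"))
  gg <- ggplot(scatter, aes(score, pred, colour = patient_id)) +
    geom_abline(linetype = "dashed") +
    geom_point(alpha = 0.6, size = 0.8, show.legend = FALSE) +
    labs(x = "reference recovery score", y = "predicted recovery score") +
    theme_minimal()
  ggsave(path_in_results("test_predictions.png"), gg,
         width = 5, height = 5, dpi = 150)
}
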