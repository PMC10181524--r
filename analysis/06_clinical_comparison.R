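# Clinical usability layer: average predicted profiles of the short-LOS
# (fast recovering) and long-LOS (slow recovering) groups with 10th/90th
# percentile bands, per-patient fast/slow classification, discharge
# readiness (score >= 1.8), sustained-decline flags, and an
# interpretability table of the selected features for one test patient.

source("analysis/common.R")
stopifnot_exists("predictions.csv", "cohort.json", "split.json",
                 "metrics.json", "features.csv")

cohort <- read_cohort(path_in_results("cohort.json"))
split <- jsonlite::read_json(path_in_results("split.json"),
                             simplifyVector = TRUE)
predictions <- read.csv(path_in_results("predictions.csv"),
                        stringsAsFactors = FALSE)
metrics <- jsonlite::read_json(path_in_results("metrics.json"),
                               simplifyVector = TRUE)
frames <- read.csv(path_in_results("features.csv"), stringsAsFactors = FALSE)

bands <- group_profiles(predictions, cohort,
                        los_threshold = study_config$clinical$los_threshold)
tab <- rbind(cbind(group = "short_los", bands$short_los),
             cbind(group = "long_los", bands$long_los))
write.csv(tab, path_in_results("group_profiles.csv"), row.names = FALSE)
cat(sprintf("Group bands: %d short-LOS and %d long-LOS patients\n",
            bands$short_los$n[1], bands$long_los$n[1]))

los_of <- setNames(cohort_frame(cohort)$los, cohort_frame(cohort)$patient_id)
assess <- do.call(rbind, lapply(split$test_ids, function(pid) {
  pp <- predictions[predictions$patient_id == pid, c("day", "pred")]
  cls <- classify_patient(pp, bands$short_los, bands$long_los)
  rd <- discharge_readiness(pp, study_config$clinical$readiness_threshold,
                            discharge_day = los_of[[pid]])
  dec <- decline_flags(pp, study_config$clinical$decline_k)
  data.frame(patient_id = pid, los = los_of[[pid]],
             days_fast = sum(cls$class == "fast", na.rm = TRUE),
             days_slow = sum(cls$class == "slow", na.rm = TRUE),
             days_indeterminate = sum(cls$class == "indeterminate",
                                      na.rm = TRUE),
             ready_day = rd$ready_day,
             unready_at_discharge = rd$unready_at_discharge,
             n_decline_flags = length(dec), stringsAsFactors = FALSE)
}))
write.csv(assess, path_in_results("test_assessments.csv"), row.names = FALSE)

cat(sprintf("%d/%d test patients reach discharge readiness (score >= %.1f)\n",
            sum(!is.na(assess$ready_day)), nrow(assess),
            study_config$clinical$readiness_threshold))
cat(sprintf("%d flagged unready on their recorded discharge day; %d show sustained declines\n",
            sum(assess$unready_at_discharge, na.rm = TRUE),
            sum(assess$n_decline_flags > 0)))

# interpretability table for the slowest-recovering test patient
slowest <- assess$patient_id[which.max(assess$days_slow)]
base_feats <- intersect(metrics$selected_features, names(frames))
report <- feature_frame_report(frames, slowest, base_feats,
                               hrr1_abnormal = study_config$clinical$hrr1_abnormal)
write.csv(report, path_in_results("example_feature_frame.csv"),
          row.names = FALSE)
cat("Example feature frame for slow-recovering patient", slowest, ":\n")
print(head(report, 10))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  pid <- slowest
  pp <- predictions[predictions$patient_id == pid, ]
  gg <- ggplot() +
    geom_ribbon(data = bands$short_los,
                aes(day, ymin = p10, ymax = p90, fill = "short LOS"),
                alpha = 0.25) +
    geom_ribbon(data = bands$long_los,
                aes(day, ymin = p10, ymax = p90, fill = "long LOS"),
                alpha = 0.25) +
    geom_line(data = bands$short_los, aes(day, mean, colour = "short LOS")) +
    geom_line(data = bands$long_los, aes(day, mean, colour = "long LOS")) +
    geom_line(data = pp, aes(day, pred), colour = "black") +
    geom_point(data = pp, aes(day, pred), colour = "black", size = 0.9) +
    geom_vline(xintercept = los_of[[pid]], linetype = "dotted") +
    labs(x = "post-operative day", y = "recovery score",
         colour = "group mean", fill = "10th-90th percentile",
         title = paste("Test patient", pid, "vs group bands")) +
    theme_minimal()
  ggsave(path_in_results("patient_vs_groups.png"), gg,
         width = 7, height = 4.5, dpi = 150)
}
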