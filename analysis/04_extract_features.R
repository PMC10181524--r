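# Generate the two-device sensor streams for every patient and extract
# the daily feature frame (vitals, HRV, circadian, heart-rate recovery,
# activity, and day-over-day deltas), then screen features by Pearson
# correlation with the reference score on the training patients.

source("analysis/common.R")
stopifnot_exists("cohort.json", "reference_profiles.csv", "split.json")

cohort <- read_cohort(path_in_results("cohort.json"))
dspec <- drop_spec(magnitude = unlist(study_config$drop$magnitude),
                   lead_days = unlist(study_config$drop$lead_days))
profiles <- build_reference_profiles(cohort, dspec,
                                     horizon = study_config$horizon)
split <- jsonlite::read_json(path_in_results("split.json"),
                             simplifyVector = TRUE)

gen_cfg <- do.call(generator_config,
                   c(list(n_patients = study_config$n_patients,
                          seed = study_config$seed),
                     study_config$generator))
feat_cfg <- do.call(feature_config, study_config$features)

t0 <- Sys.time()
frames <- do.call(rbind, lapply(cohort, function(p) {
  s <- generate_streams(p, profiles[[p$patient_id]], gen_cfg)
  fr <- extract_features(s, age = p$age,
                         days = 0:(study_config$horizon - 1L),
                         config = feat_cfg)
  cbind(patient_id = p$patient_id, fr, stringsAsFactors = FALSE)
}))
frames <- delta_features(frames)
cat(sprintf("Extracted %d patient-days x %d features in %.1f min\n",
            nrow(frames), ncol(frames) - 2L,
            as.numeric(Sys.time() - t0, units = "mins")))
write.csv(frames, path_in_results("features.csv"), row.names = FALSE, na = "")

miss <- colMeans(is.na(frames[, setdiff(names(frames), c("patient_id", "day"))]))
cat(sprintf("Median feature missingness %.1f%% (max %.1f%% for %s)\n",
            100 * median(miss), 100 * max(miss), names(which.max(miss))))

train_frames <- frames[frames$patient_id %in% split$train_ids, ]
r <- pearson_screen(train_frames, profiles[split$train_ids])
r <- r[order(-abs(r))]
write.csv(data.frame(feature = names(r), pearson_r = unname(r)),
          path_in_results("feature_correlations.csv"), row.names = FALSE)
cat("Strongest correlations with the reference score (training set):\n")
print(round(head(r, 12), 3))
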