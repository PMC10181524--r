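# Search 10,000 random partitions for the covariate-balanced two-thirds
# train / one-third test split (chi-square balance for gender,
# complication count and surgery type; Kolmogorov-Smirnov for age and
# LOS; the split with the largest p-value product wins).

source("analysis/common.R")
stopifnot_exists("cohort.json")

cohort <- read_cohort(path_in_results("cohort.json"))
split <- balanced_split(cohort,
                        fraction = study_config$split$fraction,
                        n_candidates = study_config$split$n_candidates,
                        seed = study_config$seed + 1L)

jsonlite::write_json(list(train_ids = split$train_ids,
                          test_ids = split$test_ids,
                          balance_score = split$balance_score,
                          per_variable_p = as.list(split$per_variable_p)),
                     path_in_results("split.json"), auto_unbox = TRUE,
                     digits = NA)
report <- split_report(split, cohort)
write.csv(report, path_in_results("split_report.csv"), row.names = FALSE)

cat(sprintf("Best of %d candidate splits: %d train / %d test\n",
            split$n_candidates, length(split$train_ids),
            length(split$test_ids)))
cat("Per-variable balance p-values:\n")
print(round(split$per_variable_p, 3))
print(report, digits = 3)
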