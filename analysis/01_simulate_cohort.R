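# Simulate the synthetic surgical cohort: demographics, length of stay,
# Clavien-Dindo graded complications, readmissions. Writes the cohort and
# a marginal summary to results/analysis/.

source("analysis/common.R")

gen_cfg <- do.call(generator_config,
                   c(list(n_patients = study_config$n_patients,
                          seed = study_config$seed),
                     study_config$generator))
cohort <- generate_cohort(gen_cfg)
write_cohort(cohort, path_in_results("cohort.json"))

df <- cohort_frame(cohort)
summary_tab <- data.frame(
  quantity = c("patients", "median LOS (days)", "mean LOS (days)",
               "patients with >= 1 complication", "complication events",
               "readmissions", "mean age (years)", "% female"),
  value = c(nrow(df), median(df$los), round(mean(df$los), 1),
            sum(df$n_complications > 0), sum(df$n_complications),
            sum(!is.na(df$readmission_day)), round(mean(df$age), 1),
            round(100 * mean(df$gender == "female"), 1))
)
write.csv(summary_tab, path_in_results("cohort_summary.csv"), row.names = FALSE)

cat("Simulated", nrow(df), "patients; median LOS", median(df$los),
    "days; ", sum(df$n_complications > 0), "patients with complications\n")
print(table(df$surgery_type))
cat("Cohort written to", path_in_results("cohort.json"), "\n")
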