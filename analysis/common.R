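# Shared study configuration for the numbered analysis scripts.
# Run the scripts in order from the repository root:
#   Rscript analysis/01_simulate_cohort.R
#   Rscript analysis/02_reference_profiles.R
#   ...
# Each script reads its inputs from results/ and appends its own outputs.

library(postoprecovery)

results_dir <- "results/analysis"
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

# The simulated study: 125 patients, two-thirds training split searched
# over 10,000 candidates, sensor cadences thinned to one wrist sample per
# 15 s and one chest sample per minute (daily features are insensitive to
# this; see the package vignette).
study_document <- list(
  seed = 20230501L,
  n_patients = 125L,
  generator = list(cadence = list(chest_hr = 60, chest_rr = 60,
                                  chest_act = 60, wrist = 15, ibi = 15)),
  split = list(n_candidates = 10000L),
  features = list(welch_resample_hz = 1),
  model = list(grid = list(eta = c(0.1, 0.3), max_depth = c(2L, 4L),
                           nrounds = 300L, subsample = 0.9)),
  screen_top_n = 16L,
  eliminate = TRUE
)
study_config <- validate_config(study_document)

path_in_results <- function(name) file.path(results_dir, name)

stopifnot_exists <- function(...) {
  for (f in c(...)) {
    if (!file.exists(path_in_results(f))) {
      stop("missing ", path_in_results(f),
           "; run the earlier analysis scripts first", call. = FALSE)
    }
  }
}
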