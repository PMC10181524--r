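# Shared fixtures: small cohorts and hand-built streams, generated in code.

# reduced sampling cadences keep test cohorts fast while leaving every
# feature computable
quick_cadence <- list(chest_hr = 30, chest_rr = 30, chest_act = 30,
                      wrist = 15, ibi = 10)

quick_config <- function(n_patients = 6L, seed = 42L, cadence = list(), ...) {
  generator_config(n_patients = n_patients, seed = seed,
                   cadence = utils::modifyList(quick_cadence, cadence), ...)
}

noise_free <- function() {
  list(hr = 0, rr = 0, ibi_jitter = 0, steps_frac = 0, upright = 0,
       circ = 0, actcount = 0, walkspeed = 0)
}

# feature config that ignores the daily-coverage gate, for tiny hand-built
# series
fc0 <- function(...) feature_config(min_coverage = 0, ...)

# a (t, value) stream covering one block of day `day`
stream_df <- function(values, day = 0, dt = 1, start = 0) {
  t <- day * 86400 + start + seq_along(values) * dt - dt
  data.frame(t = t, value = values)
}

# a profile whose latent score is a given constant on every day
flat_profile <- function(score, horizon = 21L) {
  p <- base_profile(los = 8, horizon = horizon)
  p$score <- rep(score, length(p$day))
  p
}

# minimal synthetic patient without sampling
fixed_patient <- function(id = "PX01", age = 60, los = 8,
                          complications = list()) {
  list(patient_id = id, age = age, gender = "female", surgery_type = "Other",
       los = as.integer(los), complications = complications,
       readmission_day = NA_integer_)
}
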