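#' Generator configuration
#'
#' Settings for the synthetic cohort and sensor-stream generator. The
#' cohort emulates a major abdominal cancer surgery population monitored
#' with a chest patch (HR, RR, activity level, posture; 14 days) and a
#' wrist band (HR, inter-beat intervals, steps, walking speed, activity
#' counts, active/sedentary classification, energy expenditure; 21 days,
#' with one daily charging gap). Every signal parameter is a deterministic
#' function of the patient's latent daily recovery score plus configured
#' noise, so daily activity, circadian amplitude and heart-rate recovery
#' all rise as the patient recovers.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer seed; the generator is fully reproducible given it.
#' @param los_meanlog,los_sdlog log-normal LOS parameters (median
#'   `exp(los_meanlog)` = 8 days; right-skewed so the mean sits near 11).
#' @param los_max LOS truncation in days, keeps discharge inside the wear
#'   period.
#' @param complication_rate probability that a patient has at least one
#'   complication.
#' @param complication_count_probs probabilities of 1, 2 or 3 complications
#'   given at least one.
#' @param cd_grade_probs sampling weights for CD grades 1-4 of an event.
#' @param readmission_rate probability of readmission after discharge.
#' @param gender_p_female,surgery_probs demographic sampling weights.
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param effect per-unit-latent-score signal gains, see Details.
#' @param noise per-channel noise levels; set all to 0 for a noise-free
#'   cohort.
#' @param cadence sampling intervals in seconds per channel group.
#' @param gap_minutes length-2 range of the daily wrist charging gap in
#'   minutes; `c(0, 0)` disables the gap.
#' @param chest_days,wrist_days wear period per device.
#'
#' @details `effect` entries (all per unit of latent score above 1.0):
#' `steps` daily step gain; `upright` upright hours gain; `walk_hours`
#' hours walked gain; `circ_base`/`circ` circadian day-night HR amplitude
#' intercept and gain (bpm); `hr_rest_base`/`hr_rest` resting HR intercept
#' and decrease (bpm); `hrr_rate_base`/`hrr_rate` post-exercise HR decay
#' rate intercept and gain (1/s); `walkspeed_base`/`walkspeed` (m/s);
#' `activity_onset` latent score above which exercise bouts are emitted;
#' `n_bouts` bouts per active day; `bout_peak_frac` bout peak as a fraction
#' of the age-predicted maximum HR (220 - age); `rr_mean` mean respiration
#' rate (breaths/min, not recovery-linked).
#'
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_patients = 125L,
                             seed = 1L,
                             los_meanlog = log(8),
                             los_sdlog = 0.55,
                             los_max = 20L,
                             complication_rate = 42 / 125,
                             complication_count_probs = c(33, 6, 3) / 42,
                             cd_grade_probs = c(0.4, 0.3, 0.2, 0.1),
                             readmission_rate = 0.08,
                             gender_p_female = 57 / 125,
                             surgery_probs = c(ER = 22, HIPEC = 23,
                                               `PPPD/Whipple` = 17,
                                               `LAR+IORT` = 19, `LAR-IORT` = 4,
                                               Other = 40) / 125,
                             age_mean = 62, age_sd = 10, age_range = c(30, 85),
                             effect = list(),
                             noise = list(),
                             cadence = list(),
                             gap_minutes = c(30, 90),
                             chest_days = 14L,
                             wrist_days = 21L) {
  effect_def <- list(
    steps = 2500, upright = 8, walk_hours = 0.5,
    circ_base = 2, circ = 8,
    hr_rest_base = 80, hr_rest = 10,
    hrr_rate_base = 0.001, hrr_rate = 0.006,
    walkspeed_base = 0.8, walkspeed = 0.4,
    activity_onset = 1.25, n_bouts = 2L, bout_peak_frac = 0.8,
    rr_mean = 16
  )
  noise_def <- list(hr = 3, rr = 1.5, ibi_jitter = 25,
                    steps_frac = 0.15, upright = 0.15, circ = 0.75,
                    actcount = 25, walkspeed = 0.1)
  cadence_def <- list(chest_hr = 8, chest_rr = 1, chest_act = 8,
                      wrist = 1, ibi = 1)
  bad <- setdiff(names(effect), names(effect_def))
  if (length(bad)) stop("unknown effect field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(names(noise), names(noise_def))
  if (length(bad)) stop("unknown noise field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(names(cadence), names(cadence_def))
  if (length(bad)) stop("unknown cadence field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    los_meanlog = los_meanlog, los_sdlog = los_sdlog,
    los_max = as.integer(los_max),
    complication_rate = complication_rate,
    complication_count_probs = complication_count_probs,
    cd_grade_probs = cd_grade_probs,
    readmission_rate = readmission_rate,
    gender_p_female = gender_p_female,
    surgery_probs = surgery_probs,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    effect = utils::modifyList(effect_def, effect),
    noise = utils::modifyList(noise_def, noise),
    cadence = utils::modifyList(cadence_def, cadence),
    gap_minutes = gap_minutes,
    chest_days = as.integer(chest_days), wrist_days = as.integer(wrist_days)
  )
  probs <- c(complication_rate = cfg$complication_rate,
             readmission_rate = cfg$readmission_rate,
             gender_p_female = cfg$gender_p_female)
  for (nm in names(probs)) {
    if (is.na(probs[[nm]]) || probs[[nm]] < 0 || probs[[nm]] > 1) {
      stop(sprintf("configuration error: %s must be a probability in [0,1]", nm),
           call. = FALSE)
    }
  }
  if (cfg$n_patients < 2L) {
    stop("configuration error: n_patients must be >= 2", call. = FALSE)
  }
  if (any(cfg$gap_minutes < 0) || cfg$gap_minutes[1] > cfg$gap_minutes[2]) {
    stop("configuration error: gap_minutes must be an increasing range >= 0",
         call. = FALSE)
  }
  if (any(unlist(cfg$cadence) <= 0)) {
    stop("configuration error: cadence values must be positive seconds",
         call. = FALSE)
  }
  if (any(unlist(cfg$noise) < 0)) {
    stop("configuration error: noise levels must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Stable small seed derived from the global seed and a patient id, so each
# patient's streams are individually reproducible.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 48271 + h * 911) %% 2147483629)
}

#' Generate a synthetic patient cohort
#'
#' Samples demographics (age, gender, surgery type), hospital length of
#' stay, complication events with Clavien-Dindo grades, and readmissions,
#' with marginal frequencies emulating a major abdominal cancer surgery
#' cohort of 125 patients (about one third with complications, median LOS
#' 8 days).
#'
#' @param config a [generator_config()].
#' @return list of patient records: `patient_id`, `age`, `gender`,
#'   `surgery_type`, `los`, `complications` (list of `day`, `cd_grade`,
#'   `location`), `readmission_day` (or `NA`).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                         config$age_range[1]), config$age_range[2]))
  gender <- ifelse(stats::runif(n) < config$gender_p_female, "female", "male")
  surgery <- sample(names(config$surgery_probs), n, replace = TRUE,
                    prob = config$surgery_probs)
  los <- pmin(pmax(round(stats::rlnorm(n, config$los_meanlog, config$los_sdlog)), 2L),
              config$los_max)
  has_comp <- stats::runif(n) < config$complication_rate
  lapply(seq_len(n), function(i) {
    comps <- list()
    if (has_comp[i]) {
      n_comp <- sample(1:3, 1, prob = config$complication_count_probs)
      days <- sort(sample(seq_len(min(los[i] + 4L, 20L)), n_comp))
      comps <- lapply(days, function(d) {
        list(day = as.integer(d),
             cd_grade = sample(1:4, 1, prob = config$cd_grade_probs),
             location = if (d <= los[i]) "hospital" else "home")
      })
    }
    readm <- NA_integer_
    if (stats::runif(1) < config$readmission_rate) {
      readm <- as.integer(min(los[i] + sample(2:6, 1), 21L))
    }
    list(patient_id = ids[i], age = age[i], gender = gender[i],
         surgery_type = surgery[i], los = as.integer(los[i]),
         complications = comps, readmission_day = readm)
  })
}

#' Cohort as a one-row-per-patient data frame
#'
#' @param cohort list of patient records.
#' @return data.frame with demographics, `los`, `n_complications`,
#'   `readmission_day`.
#' @export
cohort_frame <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort, `[[`, character(1), "patient_id"),
    age = vapply(cohort, `[[`, numeric(1), "age"),
    gender = vapply(cohort, `[[`, character(1), "gender"),
    surgery_type = vapply(cohort, `[[`, character(1), "surgery_type"),
    los = vapply(cohort, function(p) as.numeric(p$los), numeric(1)),
    n_complications = vapply(cohort, function(p) length(p$complications),
                             numeric(1)),
    readmission_day = vapply(cohort, function(p) as.numeric(p$readmission_day),
                             numeric(1)),
    stringsAsFactors = FALSE
  )
}
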