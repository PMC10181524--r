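#' Heart rate by activity context
#'
#' Mean heart rate during walking, upright, sedentary, active and inactive
#' periods, plus the active-minus-inactive difference, and splits at high
#' vs low wrist activity counts (threshold 2000 counts/s) and high vs low
#' chest activity levels (at or below level 3 is "in rest").
#'
#' @param streams a `sensor_streams` object.
#' @param day post-op day index.
#' @param config a [feature_config()].
#' @return named numeric vector of context means (bpm); a context absent
#'   that day yields `NA` for its feature.
#' @export
hr_by_context <- function(streams, day, config = feature_config()) {
  hr <- streams$wrist_hr
  flag <- function(df, test) {
    if (nrow(df) == 0L) return(df)
    data.frame(t = df$t, value = as.numeric(test(df$value)))
  }
  walking <- flag(streams$wrist_walkspeed, function(v) v > 0)
  upright <- flag(streams$chest_posture, function(v) v == "upright")
  active <- streams$wrist_pct_active
  inactive <- flag(streams$wrist_pct_active, function(v) v == 0)
  sedentary <- streams$wrist_sedentary
  hi_ac <- flag(streams$wrist_actcount, function(v) v > config$actcount_threshold)
  lo_ac <- flag(streams$wrist_actcount, function(v) v <= config$actcount_threshold)
  hi_al <- flag(streams$chest_actlevel, function(v) v > config$actlevel_threshold)
  lo_al <- flag(streams$chest_actlevel, function(v) v <= config$actlevel_threshold)
  act <- hr_context_mean(hr, active, day)
  inact <- hr_context_mean(hr, inactive, day)
  c(hr_walking = hr_context_mean(hr, walking, day),
    hr_upright = hr_context_mean(hr, upright, day),
    hr_sedentary = hr_context_mean(hr, sedentary, day),
    hr_active = act,
    hr_inactive = inact,
    hr_active_minus_inactive = act - inact,
    hr_high_actcount = hr_context_mean(hr, hi_ac, day),
    hr_low_actcount = hr_context_mean(hr, lo_ac, day),
    hr_high_actlevel = hr_context_mean(hr, hi_al, day),
    hr_low_actlevel = hr_context_mean(hr, lo_al, day))
}

#' Daily activity summaries
#'
#' Steps per day, mean walking speed, hours walking, mean activity counts,
#' percentage active time, sedentary hours, active energy expenditure,
#' upright hours and mean chest activity level.
#'
#' @inheritParams hr_by_context
#' @return named numeric vector; a channel absent that day yields `NA` for
#'   its features.
#' @export
activity_daily <- function(streams, day, config = feature_config()) {
  out <- c(steps = NA_real_, walkspeed = NA_real_, hours_walking = NA_real_,
           actcount_mean = NA_real_, pct_active = NA_real_,
           sedentary_hours = NA_real_, aee = NA_real_,
           upright_hours = NA_real_, actlevel_mean = NA_real_)
  st <- day_slice(streams$wrist_steps, day)
  if (nrow(st) > 0L) out["steps"] <- sum(st$value)
  ws <- day_slice(streams$wrist_walkspeed, day)
  if (nrow(ws) > 0L) {
    dt <- stream_dt(streams$wrist_walkspeed)
    moving <- ws$value > 0
    out["walkspeed"] <- if (any(moving)) mean(ws$value[moving]) else NA_real_
    out["hours_walking"] <- sum(moving) * dt / 3600
  }
  ac <- day_slice(streams$wrist_actcount, day)
  if (nrow(ac) > 0L) out["actcount_mean"] <- mean(ac$value)
  pa <- day_slice(streams$wrist_pct_active, day)
  if (nrow(pa) > 0L) out["pct_active"] <- 100 * mean(pa$value > 0)
  sed <- day_slice(streams$wrist_sedentary, day)
  if (nrow(sed) > 0L) {
    out["sedentary_hours"] <- sum(sed$value > 0) * stream_dt(streams$wrist_sedentary) / 3600
  }
  ae <- day_slice(streams$wrist_aee, day)
  if (nrow(ae) > 0L) out["aee"] <- sum(ae$value)
  pos <- day_slice(streams$chest_posture, day)
  if (nrow(pos) > 0L) {
    out["upright_hours"] <- sum(pos$value == "upright") *
      stream_dt(streams$chest_posture) / 3600
  }
  al <- day_slice(streams$chest_actlevel, day)
  if (nrow(al) > 0L) out["actlevel_mean"] <- mean(al$value)
  out
}

#' Names of the daily base features
#' @return character vector of the feature columns produced by
#'   [extract_features()] (before delta columns).
#' @export
feature_names <- function() {
  c("hr_mean", "hr_var", "rr_mean", "rr_var", "rhr",
    "circ_day_night", "circ_peak_nadir",
    "sdnn", "rmssd", "pnn50", "vlf", "lf", "hf", "lf_hf_ratio",
    "hrr1", "hrr2", "hrr_time",
    "hr_walking", "hr_upright", "hr_sedentary", "hr_active", "hr_inactive",
    "hr_active_minus_inactive", "hr_high_actcount", "hr_low_actcount",
    "hr_high_actlevel", "hr_low_actlevel",
    "steps", "walkspeed", "hours_walking", "actcount_mean", "pct_active",
    "sedentary_hours", "aee", "upright_hours", "actlevel_mean")
}

#' Extract the daily feature frame for one patient
#'
#' Computes every daily feature of the pipeline from raw two-device
#' streams: heart-rate and respiration mean/variance, resting HR,
#' circadian metrics, time- and frequency-domain HRV, heart-rate recovery
#' after exercise, heart rate by activity context, and activity
#' summaries. Respiration comes from the chest patch (more reliable at the
#' ribcage); heart-rate-derived features come from the wrist band (longer
#' coverage).
#'
#' @param streams a `sensor_streams` object.
#' @param age patient age in years (for the exercise-bout HR threshold);
#'   defaults to the age recorded on the streams.
#' @param days integer vector of post-op days to extract.
#' @param config a [feature_config()].
#' @return data.frame with `day` and one column per [feature_names()]
#'   entry; missing features are `NA`.
#' @export
extract_features <- function(streams, age = attr(streams, "age"),
                             days = 0:20, config = feature_config()) {
  # pre-split every channel by day so each daily operation touches only
  # that day's samples
  split_by_day <- function(df) {
    if (nrow(df) == 0L) return(list())
    dc <- floor(df$t / 86400)  # t is day-ordered, so days form runs
    idx <- c(0L, which(diff(dc) != 0L), nrow(df))
    out <- lapply(seq_len(length(idx) - 1L),
                  function(i) df[(idx[i] + 1L):idx[i + 1L], , drop = FALSE])
    names(out) <- as.character(dc[idx[-1]])
    out
  }
  by_day <- lapply(streams, split_by_day)
  slice <- function(d) {
    out <- lapply(names(streams), function(ch) {
      sub <- by_day[[ch]][[as.character(d)]]
      if (is.null(sub)) streams[[ch]][0, , drop = FALSE] else sub
    })
    names(out) <- names(streams)
    attributes(out) <- c(attributes(out),
                         list(class = "sensor_streams",
                              patient_id = attr(streams, "patient_id"),
                              age = attr(streams, "age")))
    out
  }
  rows <- lapply(days, function(d) {
    streams <- slice(d)
    hr <- daily_vital_stats(streams$wrist_hr, d, config)
    rr <- daily_vital_stats(streams$chest_rr, d, config)
    hrv_t <- hrv_time_domain(streams$wrist_ibi, d, config)
    hrv_f <- hrv_frequency_domain(streams$wrist_ibi, d, config)
    bouts <- detect_exercise_bouts(streams$wrist_hr, age, d, config)
    hrr <- heart_rate_recovery(bouts, streams$wrist_hr, d, config)
    ctx <- hr_by_context(streams, d, config)
    act <- activity_daily(streams, d, config)
    c(day = d,
      hr_mean = unname(hr["mean"]), hr_var = unname(hr["var"]),
      rr_mean = unname(rr["mean"]), rr_var = unname(rr["var"]),
      rhr = resting_heart_rate(streams$wrist_hr, streams$wrist_actcount, d,
                               inactive_max = config$actcount_threshold, config),
      circ_day_night = circadian_day_night(streams$wrist_hr, d, config),
      circ_peak_nadir = circadian_peak_nadir(streams$wrist_hr, d, config),
      hrv_t, hrv_f, hrr, ctx, act)
  })
  out <- as.data.frame(do.call(rbind, rows))
  stopifnot(identical(names(out), c("day", feature_names())))
  out
}

#' Feature frames for a whole cohort
#'
#' @param streams_by_patient named list of `sensor_streams`, one per
#'   patient id.
#' @param cohort list of patient records (supplies ages).
#' @param days post-op days to extract.
#' @param config a [feature_config()].
#' @param add_delta append day-over-day delta columns via
#'   [delta_features()].
#' @return data.frame, one row per patient-day, with `patient_id`, `day`,
#'   feature columns and (optionally) `delta_` columns.
#' @export
cohort_features <- function(streams_by_patient, cohort, days = 0:20,
                            config = feature_config(), add_delta = TRUE) {
  ages <- stats::setNames(vapply(cohort, `[[`, numeric(1), "age"),
                          vapply(cohort, `[[`, character(1), "patient_id"))
  frames <- lapply(names(streams_by_patient), function(pid) {
    fr <- extract_features(streams_by_patient[[pid]], age = ages[[pid]],
                           days = days, config = config)
    cbind(patient_id = pid, fr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, frames)
  rownames(out) <- NULL
  if (add_delta) out <- delta_features(out)
  out
}

#' Day-over-day delta features
#'
#' For every feature column, `delta_x(day) = x(day) - x(day - 1)` within a
#' patient. The delta is missing when either operand is missing and on
#' each patient's first day.
#'
#' @param frames feature frame with `patient_id`, `day` and feature
#'   columns.
#' @return the frame with a `delta_` column appended per feature.
#' @export
delta_features <- function(frames) {
  feat_cols <- setdiff(names(frames), c("patient_id", "day"))
  feat_cols <- feat_cols[!startsWith(feat_cols, "delta_")]
  ord <- order(frames$patient_id, frames$day)
  frames <- frames[ord, , drop = FALSE]
  for (fc in feat_cols) {
    x <- frames[[fc]]
    lag <- c(NA_real_, x[-length(x)])
    same_patient <- c(FALSE, frames$patient_id[-1] == frames$patient_id[-nrow(frames)])
    consecutive <- c(FALSE, diff(frames$day) == 1)
    delta <- ifelse(same_patient & consecutive, x - lag, NA_real_)
    frames[[paste0("delta_", fc)]] <- delta
  }
  rownames(frames) <- NULL
  frames
}

#' Screen features by correlation with the reference score
#'
#' Pearson correlation between each feature and the reference recovery
#' score over all patient-days where both are present.
#'
#' @param frames feature frame (`patient_id`, `day`, features).
#' @param profiles named list of `recovery_profile`.
#' @param min_pairs minimum number of complete pairs required.
#' @return named numeric vector of correlations (`NA` where undefined:
#'   too few pairs or zero variance).
#' @export
pearson_screen <- function(frames, profiles, min_pairs = 3L) {
  ref <- profiles_frame(profiles)
  merged <- merge(frames, ref, by = c("patient_id", "day"))
  feat_cols <- setdiff(names(merged), c("patient_id", "day", "score"))
  vapply(feat_cols, function(fc) {
    ok <- !is.na(merged[[fc]]) & !is.na(merged$score)
    if (sum(ok) < min_pairs) return(NA_real_)
    x <- merged[[fc]][ok]; y <- merged$score[ok]
    if (pop_var(x) == 0 || pop_var(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
}
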