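#' Feature-extraction configuration
#'
#' Thresholds and windows for the daily feature extractors. Defaults follow
#' common clinical conventions: day window 08:00-22:00 and night window
#' 00:00-06:00 for the circadian day-night heart-rate difference; standard
#' HRV task-force frequency bands (VLF 0.0033-0.04 Hz, LF 0.04-0.15 Hz, HF
#' 0.15-0.4 Hz); exercise-bout detection at 70% of the age-predicted
#' maximum heart rate (220 - age); activity-count split at 2000 counts/s
#' and chest activity-level split at level 3 ("in rest" at or below 3).
#' A daily feature is treated as missing when less than `min_coverage` of
#' the day's expected samples are present.
#'
#' @param ... overrides for any default listed in the function definition.
#' @return a `feature_config` list.
#' @export
feature_config <- function(...) {
  cfg <- list(
    day_window = c(8, 22), night_window = c(0, 6),
    min_coverage = 0.3,
    peak_nadir_min_hours = 4,
    rhr_decile = 0.1,
    hrv_min_intervals = 10,
    welch_resample_hz = 4, welch_segment_s = 300, welch_overlap = 0.5,
    vlf_band = c(0.0033, 0.04), lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
    bout_threshold_frac = 0.7, bout_refractory_s = 300, bout_min_s = 30,
    hrr_drop_bpm = 10, hrr_window_s = 600,
    actcount_threshold = 2000, actlevel_threshold = 3
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown feature_config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(utils::modifyList(cfg, over), class = "feature_config")
}

# rows of a (t, value) stream falling in post-op day `day`
day_slice <- function(stream, day) {
  stream[stream$t >= day * 86400 & stream$t < (day + 1) * 86400, , drop = FALSE]
}

# typical sampling interval of a stream, for coverage checks
stream_dt <- function(stream) {
  if (nrow(stream) < 2L) return(NA_real_)
  stats::median(diff(stream$t))
}

coverage_ok <- function(n, dt, min_frac) {
  !is.na(dt) && n * dt / 86400 >= min_frac
}

# population variance (divide by n); the convention used throughout
pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  mean((x - mean(x))^2)
}

# carry the most recent label value forward onto query times
align_values <- function(label, t) {
  if (nrow(label) == 0L) return(rep(NA, length(t)))
  idx <- findInterval(t, label$t)
  out <- rep(if (is.character(label$value)) NA_character_ else NA_real_, length(t))
  out[idx > 0] <- label$value[idx[idx > 0]]
  out
}

#' Daily mean and variance of a vital sign
#'
#' @param stream data.frame with `t` (seconds) and `value`.
#' @param day post-op day index (0 = day of surgery).
#' @param config a [feature_config()].
#' @return named numeric `c(mean, var)`; both `NA` when the day has too few
#'   samples. Variance uses the population convention (divide by n).
#' @export
daily_vital_stats <- function(stream, day, config = feature_config()) {
  d <- day_slice(stream, day)
  if (nrow(d) == 0L ||
      !coverage_ok(nrow(d), stream_dt(stream), config$min_coverage)) {
    return(c(mean = NA_real_, var = NA_real_))
  }
  c(mean = mean(d$value), var = pop_var(d$value))
}

#' Daily resting heart rate
#'
#' Mean of the lowest decile of heart-rate samples taken during inactive
#' periods of the day (activity measure at or below `inactive_max`).
#'
#' @param hr heart-rate stream.
#' @param activity activity stream (e.g. wrist activity counts or chest
#'   activity level), carried forward onto the heart-rate timestamps.
#' @param day post-op day index.
#' @param inactive_max largest activity value still counted as inactive.
#' @param config a [feature_config()].
#' @return resting HR in bpm, or `NA` when no inactive samples exist.
#' @export
resting_heart_rate <- function(hr, activity, day, inactive_max,
                               config = feature_config()) {
  d <- day_slice(hr, day)
  if (nrow(d) == 0L) return(NA_real_)
  act <- align_values(day_slice(activity, day), d$t)
  x <- d$value[!is.na(act) & act <= inactive_max]
  if (!length(x)) return(NA_real_)
  k <- max(1L, floor(length(x) * config$rhr_decile))
  mean(sort(x)[seq_len(k)])
}

#' Circadian day-night heart-rate difference
#'
#' Mean HR in the day window minus mean HR in the night window; positive
#' when the daytime heart rate exceeds the nighttime heart rate.
#'
#' @inheritParams daily_vital_stats
#' @param hr heart-rate stream.
#' @return difference in bpm, `NA` if either window is empty.
#' @export
circadian_day_night <- function(hr, day, config = feature_config()) {
  d <- day_slice(hr, day)
  if (nrow(d) == 0L) return(NA_real_)
  h <- (d$t - day * 86400) / 3600
  dw <- config$day_window; nw <- config$night_window
  day_hr <- d$value[h >= dw[1] & h < dw[2]]
  night_hr <- d$value[h >= nw[1] & h < nw[2]]
  if (!length(day_hr) || !length(night_hr)) return(NA_real_)
  mean(day_hr) - mean(night_hr)
}

#' Circadian peak-nadir heart-rate amplitude
#'
#' Difference between the largest and smallest hourly mean HR of the day.
#'
#' @inheritParams circadian_day_night
#' @return amplitude in bpm, `NA` when fewer than
#'   `config$peak_nadir_min_hours` hours carry data.
#' @export
circadian_peak_nadir <- function(hr, day, config = feature_config()) {
  d <- day_slice(hr, day)
  if (nrow(d) == 0L) return(NA_real_)
  hour <- floor((d$t - day * 86400) / 3600)
  m <- tapply(d$value, hour, mean)
  if (length(m) < config$peak_nadir_min_hours) return(NA_real_)
  max(m) - min(m)
}

#' Mean heart rate within a labelled context
#'
#' @param hr heart-rate stream.
#' @param flag logical-valued stream marking the context (carried forward
#'   onto heart-rate timestamps).
#' @param day post-op day index.
#' @return mean HR in bpm over samples where the context holds, `NA` when
#'   the context never occurs that day.
#' @export
hr_context_mean <- function(hr, flag, day) {
  d <- day_slice(hr, day)
  if (nrow(d) == 0L) return(NA_real_)
  f <- align_values(day_slice(flag, day), d$t)
  x <- d$value[!is.na(f) & f > 0]
  if (!length(x)) return(NA_real_)
  mean(x)
}
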