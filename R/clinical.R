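#' Group recovery profiles with percentile bands
#'
#' Splits the cohort into fast recoverers (short LOS, at or below the
#' threshold) and slow recoverers (long LOS) and summarises predicted
#' scores per post-op day within each group: mean plus 10th and 90th
#' percentile bands. The default threshold of 8 days is the median LOS of
#' a typical training cohort. Percentiles use linear interpolation
#' between order statistics.
#'
#' @param predictions data.frame `patient_id`, `day`, `pred` (train and
#'   test patients alike).
#' @param cohort list of patient records or a [cohort_frame()].
#' @param los_threshold LOS (days) separating short from long stays.
#' @return list of two `group_profile` data.frames (`short_los`,
#'   `long_los`), each with `day`, `mean`, `p10`, `p90`, `n`.
#' @export
group_profiles <- function(predictions, cohort, los_threshold = 8) {
  df <- if (is.data.frame(cohort)) cohort else cohort_frame(cohort)
  los <- stats::setNames(df$los, df$patient_id)
  predictions$los <- los[predictions$patient_id]
  short <- predictions[predictions$los <= los_threshold, ]
  long <- predictions[predictions$los > los_threshold, ]
  if (nrow(short) == 0L) stop("input error: short_los group is empty", call. = FALSE)
  if (nrow(long) == 0L) stop("input error: long_los group is empty", call. = FALSE)
  summarise <- function(d, label) {
    out <- do.call(rbind, lapply(sort(unique(d$day)), function(dy) {
      x <- d$pred[d$day == dy & !is.na(d$pred)]
      data.frame(day = dy, mean = mean(x),
                 p10 = unname(stats::quantile(x, 0.1, type = 7)),
                 p90 = unname(stats::quantile(x, 0.9, type = 7)),
                 n = length(x))
    }))
    attr(out, "group") <- label
    class(out) <- c("group_profile", "data.frame")
    out
  }
  list(short_los = summarise(short, "short_los"),
       long_los = summarise(long, "long_los"))
}

#' Classify a patient against the group bands
#'
#' Per day: `fast` when the predicted score sits inside or above the
#' short-LOS band while clearing the long-LOS 90th percentile; `slow`
#' when it sits inside or below the long-LOS band while staying under the
#' short-LOS 10th percentile; `indeterminate` in the overlap region.
#'
#' @param prediction_profile data.frame `day`, `pred` for one patient.
#' @param short,long `group_profile` tables from [group_profiles()].
#' @return data.frame `day`, `pred`, `class`.
#' @export
classify_patient <- function(prediction_profile, short, long) {
  days <- intersect(intersect(prediction_profile$day, short$day), long$day)
  if (!length(days)) stop("input error: no overlapping day range", call. = FALSE)
  out <- do.call(rbind, lapply(days, function(dy) {
    x <- prediction_profile$pred[prediction_profile$day == dy][1]
    s <- short[short$day == dy, ]; l <- long[long$day == dy, ]
    cls <- if (is.na(x)) NA_character_
      else if (x >= s$p10 && x > l$p90) "fast"
      else if (x <= l$p90 && x < s$p10) "slow"
      else "indeterminate"
    data.frame(day = dy, pred = x, class = cls, stringsAsFactors = FALSE)
  }))
  out
}

#' Discharge readiness from a predicted profile
#'
#' The first post-op day on which the predicted recovery score reaches
#' the readiness threshold (default 1.8, the score assigned on the day of
#' discharge). When a recorded discharge day is supplied, the result also
#' flags a patient who scores below the threshold on the day they were
#' actually discharged.
#'
#' @param prediction_profile data.frame `day`, `pred`.
#' @param threshold readiness threshold on the recovery-score scale.
#' @param discharge_day optional recorded discharge day.
#' @return list `ready_day` (integer or `NA` when never reached) and
#'   `unready_at_discharge` (logical, `NA` when no discharge day given).
#' @export
discharge_readiness <- function(prediction_profile, threshold = 1.8,
                                discharge_day = NULL) {
  p <- prediction_profile[order(prediction_profile$day), ]
  hit <- which(!is.na(p$pred) & p$pred >= threshold)
  ready_day <- if (length(hit)) p$day[hit[1]] else NA_integer_
  unready <- NA
  if (!is.null(discharge_day)) {
    row <- p[p$day == discharge_day, ]
    unready <- nrow(row) > 0 && !is.na(row$pred[1]) && row$pred[1] < threshold
  }
  list(ready_day = ready_day, unready_at_discharge = unready)
}

#' Flag sustained declines in a predicted profile
#'
#' Flags each day that ends a strictly decreasing run of at least
#' `k_days` consecutive daily scores (ties break a run). Sustained
#' decreases can precede complications.
#'
#' @param prediction_profile data.frame `day`, `pred`.
#' @param k_days minimum run length (>= 2).
#' @return integer vector of flagged days.
#' @export
decline_flags <- function(prediction_profile, k_days = 3L) {
  if (k_days < 2L) stop("k_days must be >= 2", call. = FALSE)
  p <- prediction_profile[order(prediction_profile$day), ]
  p <- p[!is.na(p$pred), ]
  if (nrow(p) < k_days) return(integer(0))
  dec <- c(FALSE, diff(p$pred) < 0 & diff(p$day) == 1)
  run <- 0L; flags <- integer(0)
  for (i in seq_along(dec)) {
    run <- if (dec[i]) run + 1L else 0L
    if (run >= k_days - 1L) flags <- c(flags, p$day[i])
  }
  flags
}

#' Interpretability table of the selected features
#'
#' Renders the per-day values of the model's selected features for one
#' patient, with missing heart-rate-recovery entries shown as
#' \"inactive\" (the patient had no exercise bout), other missing entries
#' as \"-\", and abnormally low HRR-1 values (below 12 bpm) marked.
#'
#' @param frames feature frame containing the patient.
#' @param patient_id the patient to render.
#' @param selected_features feature columns to show.
#' @param hrr1_abnormal threshold (bpm) below which HRR-1 is abnormal.
#' @return data.frame of formatted strings, one row per day, plus an
#'   `hrr1_abnormal` logical column when `hrr1` is among the selected
#'   features.
#' @export
feature_frame_report <- function(frames, patient_id, selected_features,
                                 hrr1_abnormal = 12) {
  sub <- frames[frames$patient_id == patient_id, , drop = FALSE]
  sub <- sub[order(sub$day), ]
  if (nrow(sub) == 0L) stop("unknown patient: ", patient_id, call. = FALSE)
  out <- data.frame(day = sub$day)
  for (fc in selected_features) {
    v <- sub[[fc]]
    txt <- ifelse(is.na(v),
                  if (fc %in% c("hrr1", "hrr2", "hrr_time")) "inactive" else "-",
                  format(round(v, 2), trim = TRUE))
    if (startsWith(fc, "delta_")) txt[is.na(v)] <- "-"
    out[[fc]] <- txt
  }
  if ("hrr1" %in% selected_features) {
    out$hrr1_abnormal <- !is.na(sub$hrr1) & sub$hrr1 < hrr1_abnormal
  }
  out
}
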