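#' Synthetic two-device sensor streams
#'
#' Generates raw chest-patch and wrist-band streams for one patient, driven
#' by the patient's latent daily recovery score (the reference profile).
#' All recovery-linked daily summaries are, in expectation, increasing
#' functions of the latent score: daily steps, upright hours, circadian
#' day-night heart-rate amplitude, and the 1-minute heart-rate recovery
#' after an exercise bout. With all noise levels at zero the increase is
#' strict, which is what makes the downstream learner's target formally
#' recoverable.
#'
#' Within a day the patient follows a simple schedule: an upright block
#' starting at 09:00 whose length grows with recovery, walking during the
#' first part of that block, and (once the latent score passes
#' `effect$activity_onset`) fixed exercise bouts whose heart-rate peak
#' reaches `bout_peak_frac` of the age-predicted maximum (220 - age) and
#' then decays exponentially at a recovery-dependent rate. Background heart
#' rate carries a circadian day/night modulation whose amplitude grows with
#' recovery while the resting level falls. Respiration rate is stationary
#' noise around `effect$rr_mean` and deliberately carries no recovery
#' signal. Wrist channels lose one contiguous block of samples per day
#' (sensor charging).
#'
#' @param patient a patient record from [generate_cohort()].
#' @param profile the patient's `recovery_profile`; must cover the wear
#'   period.
#' @param config a [generator_config()].
#' @return a `sensor_streams` object: list of per-channel data.frames with
#'   columns `t` (seconds since end of surgery) and `value`.
#' @export
generate_streams <- function(patient, profile, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (max(profile$day) < config$wrist_days - 1L) {
    stop("input error: profile does not cover the wear period", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, patient$patient_id))
  ef <- config$effect; nz <- config$noise; cad <- config$cadence
  hr_max <- 220 - patient$age
  peak_hr <- ef$bout_peak_frac * hr_max

  chest_hr <- list(); chest_rr <- list(); chest_act <- list(); chest_pos <- list()
  wrist <- list()

  for (d in seq_len(config$wrist_days) - 1L) {
    s <- profile$score[match(d, profile$day)]
    if (is.na(s)) next  # profile truncated (fatal event): no further wear
    s <- min(max(s, 0.8), 2.2)
    t0 <- d * 86400

    # -- daily schedule -----------------------------------------------------
    upright_h <- max(0, ef$upright * (s - 1) + stats::rnorm(1, 0, nz$upright))
    upright_h <- min(upright_h, 14)
    walk_h <- min(max(0, ef$walk_hours * (s - 1)), upright_h)
    up_start <- 9 * 3600; up_end <- up_start + upright_h * 3600
    walk_end <- up_start + walk_h * 3600
    bouts_on <- s >= ef$activity_onset
    bout_starts <- if (bouts_on) (c(10.5, 15.5)[seq_len(ef$n_bouts)]) * 3600 else numeric(0)
    hrr_rate <- ef$hrr_rate_base + ef$hrr_rate * (s - 1)
    rest_hr <- ef$hr_rest_base - ef$hr_rest * (s - 1)
    circ_amp <- max(0.5, ef$circ_base + ef$circ * (s - 1) + stats::rnorm(1, 0, nz$circ))

    background <- function(tod) {
      # day window 08-22 at +amp/2, night 00-06 at -amp/2, linear transitions
      h <- tod / 3600
      shape <- ifelse(h < 6, -0.5,
               ifelse(h < 8, -0.5 + (h - 6) / 2,
               ifelse(h < 22, 0.5, 0.5 - (h - 22) / 2)))
      rest_hr + circ_amp * shape
    }
    bout_shape <- function(tod) {
      # 0..1 envelope: 4-min linear ramp to a single peak, then exponential
      # decay at the recovery-dependent rate
      sh <- numeric(length(tod))
      for (b in bout_starts) {
        rel <- tod - b
        up <- rel >= 0 & rel <= 240
        dn <- rel > 240 & rel <= 1440
        sh[up] <- pmax(sh[up], rel[up] / 240)
        sh[dn] <- pmax(sh[dn], exp(-hrr_rate * (rel[dn] - 240)))
      }
      sh
    }
    hr_at <- function(tod, noise_sd) {
      bg <- background(tod)
      hr <- bg + (peak_hr - bg) * bout_shape(tod)
      pmin(pmax(hr + stats::rnorm(length(tod), 0, noise_sd), 25), 220)
    }

    # -- chest patch (days 0..chest_days-1, no gaps) ------------------------
    if (d < config$chest_days) {
      tod_hr <- seq(0, 86399, by = cad$chest_hr)
      chest_hr[[length(chest_hr) + 1L]] <-
        data.frame(t = t0 + tod_hr, value = hr_at(tod_hr, nz$hr))
      tod_rr <- seq(0, 86399, by = cad$chest_rr)
      chest_rr[[length(chest_rr) + 1L]] <-
        data.frame(t = t0 + tod_rr,
                   value = pmax(ef$rr_mean + stats::rnorm(length(tod_rr), 0, nz$rr), 4))
      tod_a <- seq(0, 86399, by = cad$chest_act)
      walking <- tod_a >= up_start & tod_a < walk_end
      upright <- tod_a >= up_start & tod_a < up_end
      in_bout <- bout_shape(tod_a) > 0.5
      lev <- rep(1, length(tod_a))
      lev[upright] <- 4; lev[walking] <- 6; lev[in_bout] <- 8
      chest_act[[length(chest_act) + 1L]] <- data.frame(t = t0 + tod_a, value = lev)
      chest_pos[[length(chest_pos) + 1L]] <-
        data.frame(t = t0 + tod_a,
                   value = ifelse(upright, "upright", "lying"),
                   stringsAsFactors = FALSE)
    }

    # -- wrist band (days 0..wrist_days-1, one charging gap per day) --------
    tod_w <- seq(0, 86399, by = cad$wrist)
    gap_len <- stats::runif(1, config$gap_minutes[1], config$gap_minutes[2]) * 60
    keep <- rep(TRUE, length(tod_w))
    if (gap_len > 0) {
      gap0 <- stats::runif(1, 0, 86400 - gap_len)
      keep <- tod_w < gap0 | tod_w >= gap0 + gap_len
    }
    tod_w <- tod_w[keep]
    nw <- length(tod_w)
    walking <- tod_w >= up_start & tod_w < walk_end
    upright <- tod_w >= up_start & tod_w < up_end
    in_bout <- bout_shape(tod_w) > 0
    active <- upright | in_bout

    hr_w <- hr_at(tod_w, nz$hr)
    total_steps <- max(0, ef$steps * (s - 1)) *
      exp(stats::rnorm(1, 0, nz$steps_frac))
    steps <- numeric(nw)
    if (any(walking) && total_steps > 0) steps[walking] <- total_steps / sum(walking)
    speed <- numeric(nw)
    speed[walking] <- pmax(ef$walkspeed_base + ef$walkspeed * (s - 1) +
                             stats::rnorm(sum(walking), 0, nz$walkspeed), 0.1)
    actcount <- rep(30, nw)
    actcount[upright] <- 800; actcount[walking] <- 3000
    actcount[in_bout] <- pmax(actcount[in_bout], 3500)
    actcount <- pmax(actcount + stats::rnorm(nw, 0, nz$actcount), 0)
    aee <- ifelse(active, 2, 0.3) * cad$wrist / 60  # kcal per sample

    tod_i <- seq(0, 86399, by = cad$ibi)
    keep_i <- if (gap_len > 0) (tod_i < gap0 | tod_i >= gap0 + gap_len) else
      rep(TRUE, length(tod_i))
    tod_i <- tod_i[keep_i]
    bg_i <- background(tod_i)
    hr_i <- bg_i + (peak_hr - bg_i) * bout_shape(tod_i)
    ibi <- 60000 / hr_i + stats::rnorm(length(tod_i), 0, nz$ibi_jitter)

    wrist[[length(wrist) + 1L]] <- list(
      hr = data.frame(t = t0 + tod_w, value = hr_w),
      ibi = data.frame(t = t0 + tod_i, value = ibi),
      steps = data.frame(t = t0 + tod_w, value = steps),
      walkspeed = data.frame(t = t0 + tod_w, value = speed),
      actcount = data.frame(t = t0 + tod_w, value = actcount),
      pct_active = data.frame(t = t0 + tod_w, value = as.numeric(active)),
      sedentary = data.frame(t = t0 + tod_w, value = as.numeric(!active)),
      aee = data.frame(t = t0 + tod_w, value = aee)
    )
  }

  bind_days <- function(lst) {
    if (!length(lst)) return(data.frame(t = numeric(0), value = numeric(0)))
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  wrist_chan <- function(ch) bind_days(lapply(wrist, `[[`, ch))
  structure(list(
    chest_hr = bind_days(chest_hr),
    chest_rr = bind_days(chest_rr),
    chest_actlevel = bind_days(chest_act),
    chest_posture = bind_days(chest_pos),
    wrist_hr = wrist_chan("hr"),
    wrist_ibi = wrist_chan("ibi"),
    wrist_steps = wrist_chan("steps"),
    wrist_walkspeed = wrist_chan("walkspeed"),
    wrist_actcount = wrist_chan("actcount"),
    wrist_pct_active = wrist_chan("pct_active"),
    wrist_sedentary = wrist_chan("sedentary"),
    wrist_aee = wrist_chan("aee")
  ), class = "sensor_streams",
  patient_id = patient$patient_id, age = patient$age)
}

#' @title Print a sensor-stream summary
#' @param x a `sensor_streams` object.
#' @param ... unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.sensor_streams <- function(x, ...) {
  cat(sprintf("<sensor_streams> patient %s\n", attr(x, "patient_id")))
  for (ch in names(x)) cat(sprintf("  %-16s %8d samples\n", ch, nrow(x[[ch]])))
  invisible(x)
}
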