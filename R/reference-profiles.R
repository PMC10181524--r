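#' Reference recovery profiles
#'
#' Daily recovery scores are not observable, so a per-patient reference
#' profile is engineered from the two events that are recorded for every
#' patient: the hospital length of stay (LOS) and any graded complications.
#' The complication-free profile is an anchored exponential
#' \deqn{R(t) = P - e^{-kt}}
#' rising from a score of `start` (1.0, start of recovery) on the day of
#' surgery towards a plateau `P` (2.0, fully recovered), and passing through
#' `discharge` (1.8) on the day of discharge. Solving the two anchors gives
#' \eqn{k = \log((P - start)/(P - discharge)) / LOS}, i.e. `log(5)/los` at
#' the default anchors. Recovery continues past discharge: the profile keeps
#' converging to the plateau at home.
#'
#' @name reference-profiles
NULL

#' Complication drop specification
#'
#' Complications pull the reference score down by an amount that grows with
#' their Clavien-Dindo (CD) severity grade: 0.02 for CD 1 and 2, 0.04 for
#' CD 3, 0.06 for CD 4. The decrease starts before the recorded event day
#' (complications are assumed to be detectable early): two days before for
#' CD 4, one day before otherwise.
#'
#' @param magnitude named numeric vector of drop depths per CD grade 1-4.
#' @param lead_days named integer vector of anticipation days per CD grade.
#' @return an object of class `drop_spec`.
#' @export
drop_spec <- function(magnitude = c(`1` = 0.02, `2` = 0.02, `3` = 0.04, `4` = 0.06),
                      lead_days = c(`1` = 1L, `2` = 1L, `3` = 1L, `4` = 2L)) {
  if (any(magnitude <= 0)) stop("drop magnitudes must be positive", call. = FALSE)
  if (any(diff(magnitude[order(as.integer(names(magnitude)))]) < 0)) {
    stop("drop magnitudes must be nondecreasing in CD grade", call. = FALSE)
  }
  if (any(lead_days < 1)) stop("lead_days must be >= 1", call. = FALSE)
  structure(list(magnitude = magnitude, lead_days = lead_days),
            class = "drop_spec")
}

#' Complication-free reference profile
#'
#' @param los hospital length of stay in days (>= 1).
#' @param horizon last post-operative day of the profile (>= los). Defaults
#'   to 21 days, the wrist-sensor wear period, so a target exists for every
#'   day that can carry features.
#' @param start score on the day of surgery (day 0).
#' @param discharge score assigned on the day of discharge (patients are not
#'   fully recovered when they go home).
#' @param plateau score of full recovery, approached asymptotically.
#' @param patient_id optional identifier carried on the profile.
#' @return a `recovery_profile`: list with `day` (0..horizon), `score`,
#'   `los`, `params` (including the solved decay rate `k`).
#' @examples
#' p <- base_profile(los = 10)
#' p$score[p$day == 0]   # 1.0
#' p$score[p$day == 10]  # 1.8
#' @export
base_profile <- function(los, horizon = 21L, start = 1.0, discharge = 1.8,
                         plateau = 2.0, patient_id = NA_character_) {
  if (length(los) != 1L || is.na(los) || los < 1) {
    stop("los must be a single day count >= 1", call. = FALSE)
  }
  if (horizon < los) stop("horizon must cover the discharge day", call. = FALSE)
  if (!(start < discharge && discharge < plateau)) {
    stop("anchors must satisfy start < discharge < plateau", call. = FALSE)
  }
  k <- log((plateau - start) / (plateau - discharge)) / los
  day <- 0:horizon
  structure(list(
    patient_id = patient_id,
    day = day,
    score = plateau - (plateau - start) * exp(-k * day),
    los = as.integer(los),
    events = list(),
    params = list(start = start, discharge = discharge, plateau = plateau, k = k)
  ), class = "recovery_profile")
}

#' @title Print a recovery-profile summary
#' @param x a `recovery_profile` object.
#' @param ... unused.
#' @return `x`, invisibly.
#' @exportS3Method base::print
print.recovery_profile <- function(x, ...) {
  cat(sprintf("<recovery_profile> patient %s, los %d, days 0-%d, %d event(s)\n",
              x$patient_id, x$los, max(x$day), length(x$events)))
  invisible(x)
}

# Deficit contributed by one complication event at (possibly fractional)
# days t. Linear ramp: zero the day before the lead window opens, full
# magnitude m on the event day; afterwards the deficit decays at the
# profile's own rate k so the score resumes convergence to the plateau.
event_deficit <- function(t, event_day, lead, m, k) {
  d <- numeric(length(t))
  ramp <- t > (event_day - lead - 1) & t <= event_day
  d[ramp] <- m * (t[ramp] - (event_day - lead - 1)) / (lead + 1)
  after <- t > event_day
  d[after] <- m * exp(-k * (t[after] - event_day))
  d
}

#' Apply complication drops to a reference profile
#'
#' Each event lowers the profile by its CD-grade magnitude, reached exactly
#' on the event day, with the decrease beginning `lead_days` before the
#' event. After the event the score resumes exponential convergence to the
#' plateau from the dropped value. Deficits of multiple events add. A CD
#' grade 5 event (death) truncates the profile at the event day.
#'
#' @param profile a `recovery_profile` from [base_profile()].
#' @param events list of events, each a list/row with `day` and `cd_grade`.
#' @param spec a [drop_spec()].
#' @return the modified `recovery_profile`.
#' @export
apply_drops <- function(profile, events, spec = drop_spec()) {
  stopifnot(inherits(profile, "recovery_profile"))
  if (length(events) == 0L) return(profile)
  k <- profile$params$k
  horizon <- max(profile$day)
  deficit <- numeric(length(profile$day))
  for (ev in events) {
    g <- as.integer(ev$cd_grade)
    if (is.na(g) || g < 1L || g > 5L) {
      stop(sprintf("unknown CD grade: %s", ev$cd_grade), call. = FALSE)
    }
    if (ev$day < 1 || ev$day > horizon) {
      stop(sprintf("event day %s outside profile horizon 1..%d", ev$day, horizon),
           call. = FALSE)
    }
    if (g == 5L) {
      profile$score[profile$day > ev$day] <- NA_real_
      next
    }
    m <- spec$magnitude[[as.character(g)]]
    lead <- spec$lead_days[[as.character(g)]]
    deficit <- deficit + event_deficit(profile$day, ev$day, lead, m, k)
  }
  profile$score <- profile$score - deficit
  profile$events <- c(profile$events, events)
  profile
}

#' Build reference profiles for a whole cohort
#'
#' @param cohort list of patient records (see [generate_cohort()]).
#' @param spec a [drop_spec()].
#' @param horizon profile horizon in days.
#' @return named list of `recovery_profile`, one per patient id.
#' @export
build_reference_profiles <- function(cohort, spec = drop_spec(), horizon = 21L) {
  profiles <- lapply(cohort, function(p) {
    prof <- base_profile(p$los, horizon = max(horizon, p$los),
                         patient_id = p$patient_id)
    apply_drops(prof, p$complications, spec)
  })
  names(profiles) <- vapply(cohort, `[[`, character(1), "patient_id")
  profiles
}

#' Reference profiles as a long table
#'
#' @param profiles named list of `recovery_profile`.
#' @return data.frame with `patient_id`, `day`, `score`.
#' @export
profiles_frame <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(patient_id = p$patient_id, day = p$day, score = p$score,
               stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}
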