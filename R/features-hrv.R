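#' Time-domain heart-rate variability
#'
#' SDNN (standard deviation of normal-to-normal inter-beat intervals,
#' population convention), RMSSD (root mean square of successive interval
#' differences) and pNN50 (percentage of successive differences larger
#' than 50 ms) over one day of inter-beat-interval data.
#'
#' @param ibi inter-beat-interval stream, `value` in milliseconds.
#' @param day post-op day index.
#' @param config a [feature_config()].
#' @return named numeric `c(sdnn, rmssd, pnn50)`; all `NA` when fewer than
#'   `config$hrv_min_intervals` intervals are present.
#' @export
hrv_time_domain <- function(ibi, day, config = feature_config()) {
  d <- day_slice(ibi, day)
  x <- d$value[!is.na(d$value)]
  if (length(x) < config$hrv_min_intervals) {
    return(c(sdnn = NA_real_, rmssd = NA_real_, pnn50 = NA_real_))
  }
  dx <- diff(x)
  c(sdnn = sqrt(pop_var(x)),
    rmssd = sqrt(mean(dx^2)),
    pnn50 = 100 * mean(abs(dx) > 50))
}

# Welch's averaged modified periodogram. x: evenly sampled series, fs in
# Hz, nperseg samples per segment (Hann window), 50% overlap by default.
# Returns data.frame(freq, psd) one-sided, density scaling (power/Hz).
welch_psd <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  scale <- fs * sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[seq_len(nf)])^2 / scale
    # one-sided: double everything except DC (and Nyquist for even nperseg)
    p[-1L] <- p[-1L] * 2
    if (nperseg %% 2 == 0) p[nf] <- p[nf] / 2
    acc <- acc + p
  }
  data.frame(freq = (seq_len(nf) - 1L) * fs / nperseg,
             psd = acc / length(starts))
}

band_power <- function(psd, band) {
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$psd[psd$freq >= band[1] & psd$freq < band[2]]) * df
}

#' Frequency-domain heart-rate variability
#'
#' The day's inter-beat intervals are interpolated onto an even grid
#' (`config$welch_resample_hz`), the power spectral density is estimated
#' with Welch's averaged-periodogram method (Hann window,
#' `config$welch_segment_s` segments, 50% overlap), and power is
#' integrated over the VLF, LF and HF bands.
#'
#' @inheritParams hrv_time_domain
#' @return named numeric `c(vlf, lf, hf, lf_hf_ratio)` (power in ms^2);
#'   all `NA` when the day holds less than two Welch segments' worth of
#'   data; the ratio alone is `NA` when HF power is zero.
#' @export
hrv_frequency_domain <- function(ibi, day, config = feature_config()) {
  out <- c(vlf = NA_real_, lf = NA_real_, hf = NA_real_, lf_hf_ratio = NA_real_)
  d <- day_slice(ibi, day)
  d <- d[!is.na(d$value), , drop = FALSE]
  if (nrow(d) < config$hrv_min_intervals) return(out)
  span <- max(d$t) - min(d$t)
  if (span < config$welch_segment_s) return(out)
  fs <- config$welch_resample_hz
  grid <- seq(min(d$t), max(d$t), by = 1 / fs)
  x <- stats::spline(d$t, d$value, xout = grid)$y
  psd <- welch_psd(x, fs, nperseg = round(config$welch_segment_s * fs),
                   overlap = config$welch_overlap)
  vlf <- band_power(psd, config$vlf_band)
  lf <- band_power(psd, config$lf_band)
  hf <- band_power(psd, config$hf_band)
  c(vlf = vlf, lf = lf, hf = hf,
    lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
}

#' Detect exercise bouts
#'
#' Maximal contiguous episodes with heart rate at or above
#' `config$bout_threshold_frac` of the age-predicted maximum (220 - age).
#' Episodes separated by less than `config$bout_refractory_s` are merged;
#' episodes shorter than `config$bout_min_s` are dropped.
#'
#' @param hr heart-rate stream.
#' @param age patient age in years.
#' @param day post-op day index.
#' @param config a [feature_config()].
#' @return list of bouts, each with `start`, `end`, `peak_time`, `peak_hr`.
#' @export
detect_exercise_bouts <- function(hr, age, day, config = feature_config()) {
  d <- day_slice(hr, day)
  if (nrow(d) == 0L) return(list())
  threshold <- config$bout_threshold_frac * (220 - age)
  above <- d$value >= threshold
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = d$t[starts[r$values]], end = d$t[ends[r$values]],
                     i0 = starts[r$values], i1 = ends[r$values])
  # merge runs separated by less than the refractory gap
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      if (runs$start[i] - merged$end[last] < config$bout_refractory_s) {
        merged$end[last] <- runs$end[i]
        merged$i1[last] <- runs$i1[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start >= config$bout_min_s, , drop = FALSE]
  lapply(seq_len(nrow(merged)), function(i) {
    idx <- merged$i0[i]:merged$i1[i]
    pk <- idx[which.max(d$value[idx])]
    list(start = merged$start[i], end = merged$end[i],
         peak_time = d$t[pk], peak_hr = d$value[pk])
  })
}

#' Heart-rate recovery after exercise
#'
#' For each bout: HRR-1 and HRR-2 are the drops from the bout's peak HR to
#' the HR one and two minutes after the peak (linear interpolation on the
#' day's samples); HRR-time is the time in seconds until the HR first
#' falls 10 bpm (`config$hrr_drop_bpm`) below the peak, searched within
#' `config$hrr_window_s`. Daily values are means over the day's bouts; a
#' bout with a truncated post-peak window is excluded from the affected
#' metric.
#'
#' @param bouts list from [detect_exercise_bouts()].
#' @param hr heart-rate stream.
#' @param day post-op day index.
#' @param config a [feature_config()].
#' @return named numeric `c(hrr1, hrr2, hrr_time)`; all `NA` on days with
#'   no qualifying bout (the patient was inactive).
#' @export
heart_rate_recovery <- function(bouts, hr, day, config = feature_config()) {
  out <- c(hrr1 = NA_real_, hrr2 = NA_real_, hrr_time = NA_real_)
  if (!length(bouts)) return(out)
  d <- day_slice(hr, day)
  dt <- stream_dt(d)
  hr1 <- c(); hr2 <- c(); ht <- c()
  for (b in bouts) {
    for (lag in c(60, 120)) {
      tq <- b$peak_time + lag
      # require a sample at/after the query time (post-peak window intact)
      if (max(d$t) >= tq - dt / 2) {
        v <- stats::approx(d$t, d$value, xout = min(tq, max(d$t)))$y
        drop <- b$peak_hr - v
        if (lag == 60) hr1 <- c(hr1, drop) else hr2 <- c(hr2, drop)
      }
    }
    post <- d[d$t > b$peak_time & d$t <= b$peak_time + config$hrr_window_s, ,
              drop = FALSE]
    hit <- which(post$value <= b$peak_hr - config$hrr_drop_bpm)
    if (length(hit)) ht <- c(ht, post$t[hit[1]] - b$peak_time)
  }
  c(hrr1 = if (length(hr1)) mean(hr1) else NA_real_,
    hrr2 = if (length(hr2)) mean(hr2) else NA_real_,
    hrr_time = if (length(ht)) mean(ht) else NA_real_)
}
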