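## Atrial-fibrillation episode detection, the per-day animal diagnosis
## rule, and R-R variability metrics.

#' Atrial-fibrillation detection criteria
#'
#' The diagnosis rule: disorganized atrial activity with irregularly
#' conducted QRS complexes lasting more than `min_episode_s` seconds in at
#' least `min_recordings_same_day` separate recordings on the same day.
#' "Disorganized atrial activity" is operationalized as R-R irregularity
#' (windowed coefficient of variation above `rr_cv_threshold`) together
#' with the absence of a consistent pre-QRS P deflection; both thresholds
#' are configurable artifact decisions, not reported values.
#'
#' @param min_episode_s Minimum qualifying episode duration (s, strict).
#' @param min_recordings_same_day Recordings with episodes needed for a
#'   positive animal-day.
#' @param recording_length_s Nominal recording length (s).
#' @param rr_cv_threshold Windowed R-R coefficient-of-variation threshold.
#' @param window_s Sliding analysis window (s).
#' @param step_s Window stride (s).
#' @param p_band_k Noise-band multiple for the P-absence check.
#' @return An object of class `af_criteria`.
#' @export
af_criteria <- function(min_episode_s = 30, min_recordings_same_day = 2L,
                        recording_length_s = 60, rr_cv_threshold = 0.15,
                        window_s = 5, step_s = 1, p_band_k = 2) {
  if (min_episode_s > recording_length_s) {
    config_error("min_episode_s must not exceed recording_length_s")
  }
  if (min_episode_s <= 0 || rr_cv_threshold <= 0 || window_s <= 0 || step_s <= 0) {
    config_error("criteria thresholds must be positive")
  }
  structure(list(
    min_episode_s = min_episode_s,
    min_recordings_same_day = as.integer(min_recordings_same_day),
    recording_length_s = recording_length_s,
    rr_cv_threshold = rr_cv_threshold,
    window_s = window_s, step_s = step_s, p_band_k = p_band_k
  ), class = "af_criteria")
}

# Consistency of atrial activity before the QRS: the per-offset median of
# R-aligned pre-QRS segments.  A sinus P wave survives the median; random-
# phase fibrillatory waves cancel, while simultaneously inflating the
# mid-diastolic noise estimate that sets the band.
p_wave_consistency <- function(ecg, beats, idx, p_band_k) {
  fs <- ecg$sampling_rate
  rr_med <- stats::median(beats$rr_ms[idx], na.rm = TRUE)
  seg_off <- round(seq(-55, -8, by = 1000 / fs) / 1000 * fs)
  noise_off <- round(seq(0.45 * rr_med, 0.55 * rr_med, by = 1000 / fs) / 1000 * fs)
  r_samp <- round(beats$time_s[idx] * fs) + 1L
  keep <- r_samp + min(seg_off) >= 1L & r_samp + max(noise_off) <= length(ecg$samples)
  r_samp <- r_samp[keep]
  if (length(r_samp) < 3L) return(TRUE)     # too few beats to call P present
  segs <- vapply(r_samp, function(r) ecg$samples[r + seg_off], numeric(length(seg_off)))
  med <- apply(segs, 1, stats::median)
  noise <- as.vector(vapply(r_samp, function(r) ecg$samples[r + noise_off],
                            numeric(length(noise_off))))
  band <- max(p_band_k * stats::sd(noise), 1e-9)
  max(abs(med)) > band
}

#' Detect atrial-fibrillation episodes
#'
#' Sliding windows are flagged as fibrillatory when (a) the coefficient of
#' variation of the R-R intervals in the window exceeds the criteria
#' threshold and (b) no consistent pre-QRS P deflection is found (median
#' aligned pre-QRS amplitude below the noise band).  Flagged windows are
#' merged and merged intervals longer than `min_episode_s` (strictly) are
#' returned.
#'
#' @param ecg An [ecg_recording()].
#' @param beats A [beat_table()]; defaults to [detect_r_peaks()] output.
#' @param criteria An [af_criteria()].
#' @return A data frame with `start_s`, `end_s`, `duration_s`, one row per
#'   qualifying episode.  A recording shorter than the analysis window
#'   returns an empty frame with a warning.
#' @export
detect_af_episodes <- function(ecg, beats = NULL, criteria = af_criteria()) {
  if (is.null(beats)) beats <- detect_r_peaks(ecg)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0))
  if (ecg$duration < criteria$window_s) {
    warning("recording shorter than the analysis window; no episodes assessed")
    return(empty)
  }
  starts <- seq(0, ecg$duration - criteria$window_s, by = criteria$step_s)
  flagged <- logical(length(starts))
  for (w in seq_along(starts)) {
    lo <- starts[w]; hi <- lo + criteria$window_s
    idx <- which(beats$time_s >= lo & beats$time_s <= hi)
    idx <- idx[!is.na(beats$rr_ms[idx]) & beats$time_s[idx] - beats$rr_ms[idx] / 1000 >= lo]
    if (length(idx) < 4L) next
    rr <- beats$rr_ms[idx]
    cv <- stats::sd(rr) / mean(rr)
    if (cv <= criteria$rr_cv_threshold) next
    flagged[w] <- !p_wave_consistency(ecg, beats, idx, criteria$p_band_k)
  }
  if (!any(flagged)) return(empty)
  iv <- cbind(starts[flagged], starts[flagged] + criteria$window_s)
  merged <- list(iv[1, ])
  if (nrow(iv) > 1) for (r in 2:nrow(iv)) {
    last <- merged[[length(merged)]]
    if (iv[r, 1] <= last[2]) {
      merged[[length(merged)]][2] <- max(last[2], iv[r, 2])
    } else {
      merged[[length(merged) + 1L]] <- iv[r, ]
    }
  }
  out <- do.call(rbind, lapply(merged, function(e) {
    data.frame(start_s = e[1], end_s = e[2], duration_s = e[2] - e[1])
  }))
  out[out$duration_s > criteria$min_episode_s, , drop = FALSE]
}

#' Per-day atrial-fibrillation diagnosis for an animal
#'
#' TRUE iff at least `min_recordings_same_day` of the animal's same-day
#' recordings contain at least one qualifying episode.
#'
#' @param episodes_per_recording List of per-recording episode frames from
#'   [detect_af_episodes()] (one element per same-day recording).
#' @param criteria An [af_criteria()].
#' @return Logical scalar.
#' @export
classify_animal_day <- function(episodes_per_recording, criteria = af_criteria()) {
  if (!length(episodes_per_recording)) config_error("need at least one recording for the animal-day")
  n_with <- sum(vapply(episodes_per_recording, function(e) nrow(e) > 0L, logical(1)))
  n_with >= criteria$min_recordings_same_day
}

#' R-R variability metrics
#'
#' SD of the instantaneous heart rate (bpm) over the first `window_s`
#' seconds, the corresponding SD of the R-R intervals (ms), and the
#' Poincare pairs of consecutive R-R intervals.
#'
#' @param beats A [beat_table()].
#' @param window_s Analysis window from the start of the recording
#'   (default 60 s); shorter recordings are analysed over the available
#'   span and flagged.
#' @return An object of class `hrv_metrics`: `hr_sd` (bpm), `rr_sd` (ms),
#'   `mean_hr` (bpm), `poincare` data frame (`rr_n`, `rr_n1`, ms),
#'   `n_intervals`, `window_short` flag.
#' @export
hrv_metrics <- function(beats, window_s = 60) {
  idx <- which(!is.na(beats$rr_ms) & beats$time_s <= window_s)
  if (length(idx) < 2L) config_error("need at least 3 beats inside the window")
  rr <- beats$rr_ms[idx]
  hr <- beats$hr_bpm[idx]
  all_rr <- beats$rr_ms[!is.na(beats$rr_ms)]
  structure(list(
    hr_sd = stats::sd(hr),
    rr_sd = stats::sd(rr),
    mean_hr = mean(hr),
    poincare = data.frame(rr_n = all_rr[-length(all_rr)], rr_n1 = all_rr[-1]),
    n_intervals = length(idx),
    window_short = max(beats$time_s) < window_s
  ), class = "hrv_metrics")
}

#' @export
print.hrv_metrics <- function(x, ...) {
  cat(sprintf("<hrv_metrics> HR %.0f +/- %.1f bpm (SD), RR SD %.1f ms, %d intervals%s\n",
              x$mean_hr, x$hr_sd, x$rr_sd, x$n_intervals,
              if (x$window_short) " [short window]" else ""))
  invisible(x)
}
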