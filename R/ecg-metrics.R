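## Beat detection and signal-averaged interval measurement for single-lead
## murine ECGs.

#' Beat table constructor
#'
#' @param r_times R-peak times in seconds, strictly increasing.
#' @param labels Per-beat labels among `"sinus"`, `"PAC"`, `"in_AF"`,
#'   `"unclassified"`.
#' @return An object of class `beat_table`: a data frame with `time_s`,
#'   `rr_ms` (interval ending at each beat; NA for the first) and
#'   `hr_bpm` (instantaneous heart rate, 60000/RR), plus `label`.
#' @export
beat_table <- function(r_times, labels = NULL) {
  r_times <- as.numeric(r_times)
  if (length(r_times) && any(diff(r_times) <= 0)) format_error("r_times must be strictly increasing")
  rr <- if (length(r_times)) c(NA_real_, diff(r_times) * 1000) else numeric(0)
  if (any(rr[-1] <= 20, na.rm = TRUE)) {
    format_error("R-R interval below the 20 ms murine refractory floor")
  }
  df <- data.frame(
    time_s = r_times,
    rr_ms = rr,
    hr_bpm = 60000 / rr,
    label = labels %||% rep("sinus", length(r_times)),
    stringsAsFactors = FALSE
  )
  class(df) <- c("beat_table", "data.frame")
  df
}

#' Detect R peaks in an ECG recording
#'
#' Band-limited differentiated-energy detector: the trace is band-passed
#' (Butterworth, zero-phase), differentiated, squared and integrated over a
#' 10 ms moving window; peaks of the resulting envelope above an adaptive
#' threshold (a fraction of the median candidate peak height) are kept with
#' a 20 ms refractory period, and each R time is refined to the raw-signal
#' extremum nearby.
#'
#' @param ecg An [ecg_recording()] sampled at >= 1000 Hz.
#' @param refractory_ms Minimum peak separation (default 20 ms).
#' @return A [beat_table()] (all labels `"sinus"`; see [detect_pac()] and
#'   [detect_af_episodes()] for relabelling).  A flat or saturated signal
#'   yields an empty table with a warning.
#' @export
detect_r_peaks <- function(ecg, refractory_ms = 20) {
  if (ecg$sampling_rate < 1000) config_error("R detection needs sampling_rate >= 1000 Hz")
  fs <- ecg$sampling_rate
  v <- ecg$samples
  if (stats::sd(v) < 1e-9) {
    warning("flat or saturated signal; no beats detected")
    return(beat_table(numeric(0), character(0)))
  }
  bp <- signal::butter(2, c(20, 250) / (fs / 2), type = "pass")
  f <- signal::filtfilt(bp, v)
  env <- c(0, diff(f))^2
  w <- max(3L, round(0.010 * fs))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0

  ref <- max(1L, round(refractory_ms / 1000 * fs))
  cand <- which(env > 4 * stats::median(env))
  cand <- cand[env[cand] >= env[pmax(cand - 1L, 1L)] & env[cand] >= env[pmin(cand + 1L, length(env))]]
  if (!length(cand)) {
    warning("no suprathreshold activity; no beats detected")
    return(beat_table(numeric(0), character(0)))
  }
  # QRS differentiated energy dwarfs P/T deflections; anchor the threshold
  # to the upper candidate quantile so atrial waves never double-count
  thr <- 0.15 * stats::quantile(env[cand], 0.95)
  peaks <- integer(0)
  last <- -Inf
  ord <- which(env > thr)
  ord <- ord[env[ord] >= env[pmax(ord - 1L, 1L)] & env[ord] >= env[pmin(ord + 1L, length(env))]]
  for (i in ord) {
    if (i - last > ref) {
      peaks <- c(peaks, i)
      last <- i
    } else if (length(peaks) && env[i] > env[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
      last <- i
    }
  }
  # refine to the raw R apex
  half <- as.integer(round(0.006 * fs))
  r_idx <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(length(v), i + half)
    lo + which.max(v[lo:hi]) - 1L
  }, numeric(1))
  r_idx <- sort(unique(r_idx))
  if (length(r_idx) > 1) r_idx <- r_idx[c(TRUE, diff(r_idx) > ref)]
  beat_table((r_idx - 1L) / fs)
}

#' Signal-average consecutive sinus beats
#'
#' R-aligned pointwise mean of `n` consecutive sinus-labeled beats whose
#' R-R intervals all lie within 10% of their median, over a window
#' spanning -0.6 to +0.4 of the median R-R interval around the R peak.
#'
#' @param ecg An [ecg_recording()].
#' @param beats A [beat_table()].
#' @param n Beats per tracing (default 10).
#' @param start Index of the first beat of the run; `NULL` picks the first
#'   qualifying run.
#' @return An object of class `signal_averaged_beat`: `waveform` (mV),
#'   `t_ms` (time axis relative to R), `r_index`, `rr_ms` (median R-R of
#'   the run), `n_beats_averaged`, `sampling_rate`, `beat_indices`.
#'   Fails with `atriakit_insufficient_sinus` when no run qualifies.
#' @export
signal_average <- function(ecg, beats, n = 10L, start = NULL) {
  runs <- if (is.null(start)) qualifying_runs(beats, n) else start
  fs <- ecg$sampling_rate
  for (s in runs) {
    idx <- s:(s + n - 1L)
    rr_med <- stats::median(beats$rr_ms[idx[-1]])
    pre <- round(0.6 * rr_med / 1000 * fs)
    post <- round(0.4 * rr_med / 1000 * fs)
    r_samp <- round(beats$time_s[idx] * fs) + 1L
    if (any(r_samp - pre < 1L) || any(r_samp + post > length(ecg$samples))) next
    acc <- rep(0, pre + post + 1L)
    for (r in r_samp) acc <- acc + ecg$samples[(r - pre):(r + post)]
    return(structure(list(
      waveform = acc / n,
      t_ms = ((-pre):post) / fs * 1000,
      r_index = pre + 1L,
      rr_ms = rr_med,
      n_beats_averaged = as.integer(n),
      sampling_rate = fs,
      beat_indices = idx
    ), class = "signal_averaged_beat"))
  }
  stop_atriakit("atriakit_insufficient_sinus",
                "no run of %d consecutive sinus beats with R-R within 10%% of their median", n)
}

# Start indices of all runs of n consecutive sinus beats with RR within
# +/-10% of the run median.
qualifying_runs <- function(beats, n) {
  nb <- nrow(beats)
  if (nb < n) return(integer(0))
  ok <- logical(nb - n + 1L)
  for (s in seq_len(nb - n + 1L)) {
    idx <- s:(s + n - 1L)
    if (any(beats$label[idx] != "sinus")) next
    rr <- beats$rr_ms[idx[-1]]
    if (anyNA(rr)) next
    med <- stats::median(rr)
    ok[s] <- all(abs(rr - med) <= 0.10 * med)
  }
  which(ok)
}

# Interpolated |v| band-crossing times used for fiducial placement:
# scanning outward/inward within a window for the first/last excursion
# beyond the noise band.
interp_crossing <- function(t_ms, v, i_out, i_in, band) {
  # crossing between the sub-band sample i_out and the supra-band i_in
  v0 <- abs(v[i_out]); v1 <- abs(v[i_in])
  if (v1 <= v0) return(t_ms[i_in])
  frac <- (band - v0) / (v1 - v0)
  t_ms[i_out] + frac * (t_ms[i_in] - t_ms[i_out])
}

#' Measure ECG intervals on a signal-averaged beat
#'
#' Noise-band fiducial rule: the baseline noise SD is estimated on the
#' isoelectric segment preceding the P wave; P and QRS onsets/offsets are
#' the first/last excursions of the averaged waveform beyond
#' `noise_band_k` times that SD inside their search windows, with linear
#' sub-sample interpolation of the band crossings.  PR is measured P onset
#' to QRS onset.
#'
#' @param sab A [signal_average()] result.
#' @param noise_band_k Band multiple `k` (default 2).
#' @param p_search_ms Width of the P search window ending just before QRS
#'   onset (default 60 ms).
#' @return An object of class `ecg_intervals` with `p_duration`,
#'   `pr_interval`, `qrs_duration` (ms), `heart_rate` (bpm), `noise_sd`
#'   (mV) and fiducials (ms relative to R).  An undetectable P wave (e.g.
#'   atrial fibrillation or sinus arrest) gives `p_duration = NaN` with
#'   `p_detected = FALSE`.
#' @export
measure_intervals <- function(sab, noise_band_k = 2, p_search_ms = 60) {
  t <- sab$t_ms
  v <- sab$waveform
  ri <- sab$r_index
  rr <- sab$rr_ms

  ns <- which(t >= -0.60 * rr & t <= -0.50 * rr)
  if (length(ns) < 4) config_error("averaged window too short for a noise segment")
  band <- max(noise_band_k * stats::sd(v[ns]), 1e-9)

  qrs_win <- which(t >= -0.25 * rr & t <= 0.25 * rr)
  # scan backward then forward from R until the waveform re-enters the band
  below <- abs(v) <= band
  i_on <- NA_integer_
  for (i in rev(qrs_win[qrs_win < ri])) if (below[i]) { i_on <- i; break }
  i_off <- NA_integer_
  for (i in qrs_win[qrs_win > ri]) if (below[i]) { i_off <- i; break }
  if (is.na(i_on) || is.na(i_off)) {
    stop_atriakit("atriakit_no_signal", "QRS bounds not found within the search window")
  }
  qrs_on <- interp_crossing(t, v, i_on, i_on + 1L, band)
  qrs_off <- interp_crossing(t, v, i_off, i_off - 1L, band)

  # A P deflection must stay beyond the band for >= 2 ms: with k = 2 a few
  # isolated noise samples always poke through the band, and a single
  # sample must not seed a fiducial.
  p_win <- which(t >= qrs_on - p_search_ms & t <= qrs_on - 2)
  supra_lgl <- abs(v[p_win]) > band
  min_run <- max(2L, as.integer(round(0.002 * sab$sampling_rate)))
  r <- rle(supra_lgl)
  ends <- cumsum(r$lengths)
  good <- which(r$values & r$lengths >= min_run)
  if (length(good)) {
    first <- p_win[ends[good[1L]] - r$lengths[good[1L]] + 1L]
    last <- p_win[ends[good[length(good)]]]
    p_on <- if (first > 1L) interp_crossing(t, v, first - 1L, first, band) else t[first]
    p_off <- if (last < length(t)) interp_crossing(t, v, last + 1L, last, band) else t[last]
    p_detected <- TRUE
  } else {
    p_on <- NaN; p_off <- NaN
    p_detected <- FALSE
  }

  structure(list(
    p_duration = p_off - p_on,
    pr_interval = qrs_on - p_on,
    qrs_duration = qrs_off - qrs_on,
    heart_rate = 60000 / rr,
    p_detected = p_detected,
    noise_sd = band / noise_band_k,
    fiducials = c(p_onset = p_on, p_offset = p_off,
                  qrs_onset = qrs_on, qrs_offset = qrs_off),
    n_beats_averaged = sab$n_beats_averaged
  ), class = "ecg_intervals")
}

#' @export
print.ecg_intervals <- function(x, ...) {
  cat(sprintf("<ecg_intervals> P %.2f ms | PR %.2f ms | QRS %.2f ms | HR %.0f bpm%s\n",
              x$p_duration, x$pr_interval, x$qrs_duration, x$heart_rate,
              if (isTRUE(x$p_detected)) "" else " [no P wave]"))
  invisible(x)
}

#' Per-recording signal-averaged interval measurement
#'
#' Applies [signal_average()] and [measure_intervals()] over sliding
#' 10-beat windows (every qualifying start, up to `max_tracings`) and
#' averages the per-tracing measurements; the quantification target is at
#' least 50 tracings per animal, so fewer qualifying windows sets a
#' quality flag rather than failing.
#'
#' @param ecg An [ecg_recording()].
#' @param beats A [beat_table()]; defaults to [detect_r_peaks()] output.
#' @param n Beats per tracing.
#' @param noise_band_k Fiducial band multiple.
#' @param max_tracings Cap on the number of sliding tracings measured.
#' @return An `ecg_intervals` object (mean over tracings) with
#'   `n_tracings` and `quality_flag` (`TRUE` when fewer than 50 tracings
#'   qualified).
#' @export
measure_ecg_intervals <- function(ecg, beats = NULL, n = 10L, noise_band_k = 2,
                                  max_tracings = 100L) {
  if (is.null(beats)) beats <- detect_r_peaks(ecg)
  runs <- qualifying_runs(beats, n)
  if (!length(runs)) {
    stop_atriakit("atriakit_insufficient_sinus",
                  "no run of %d consecutive qualifying sinus beats", n)
  }
  if (length(runs) > max_tracings) {
    runs <- runs[round(seq(1, length(runs), length.out = max_tracings))]
  }
  vals <- lapply(runs, function(s) {
    tryCatch({
      sab <- signal_average(ecg, beats, n = n, start = s)
      m <- measure_intervals(sab, noise_band_k = noise_band_k)
      c(p = m$p_duration, pr = m$pr_interval, qrs = m$qrs_duration, hr = m$heart_rate,
        p_det = as.numeric(m$p_detected))
    }, atriakit_error = function(e) NULL)   # e.g. averaging window off the recording edge
  })
  vals <- do.call(rbind, vals[!vapply(vals, is.null, logical(1))])
  if (is.null(vals) || !nrow(vals)) {
    stop_atriakit("atriakit_insufficient_sinus", "no measurable signal-averaged tracing")
  }
  out <- structure(list(
    p_duration = mean(vals[, "p"], na.rm = TRUE),
    pr_interval = mean(vals[, "pr"], na.rm = TRUE),
    qrs_duration = mean(vals[, "qrs"], na.rm = TRUE),
    heart_rate = mean(vals[, "hr"]),
    p_detected = mean(vals[, "p_det"]) > 0.5,
    n_tracings = nrow(vals),
    quality_flag = nrow(vals) < 50L
  ), class = "ecg_intervals")
  out
}

#' Label premature atrial complexes
#'
#' A beat is a PAC when its R-R interval is shorter than 80% of the median
#' of the previous five sinus intervals and the beat is not inside a
#' detected atrial fibrillation episode (AF labelling takes precedence).
#'
#' @param beats A [beat_table()] with at least 6 beats.
#' @param af_episodes Optional data frame (`start_s`, `end_s`) from
#'   [detect_af_episodes()]; beats inside episodes are labelled `"in_AF"`.
#' @return The beat table with updated labels.
#' @export
detect_pac <- function(beats, af_episodes = NULL) {
  if (nrow(beats) < 6) config_error("PAC detection needs at least 6 beats")
  lab <- beats$label
  in_af <- rep(FALSE, nrow(beats))
  if (!is.null(af_episodes) && nrow(af_episodes)) {
    for (k in seq_len(nrow(af_episodes))) {
      in_af <- in_af | (beats$time_s >= af_episodes$start_s[k] &
                          beats$time_s <= af_episodes$end_s[k])
    }
  }
  lab[in_af] <- "in_AF"
  sinus_rr <- numeric(0)
  for (i in seq_len(nrow(beats))[-1]) {
    if (in_af[i]) next
    rr <- beats$rr_ms[i]
    if (length(sinus_rr) >= 5 && rr < 0.80 * stats::median(utils::tail(sinus_rr, 5))) {
      lab[i] <- "PAC"
    } else {
      if (!in_af[i - 1L]) sinus_rr <- c(sinus_rr, rr)
      if (lab[i] != "in_AF") lab[i] <- "sinus"
    }
  }
  beats$label <- lab
  beats
}
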