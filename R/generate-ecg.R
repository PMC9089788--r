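## Synthetic single-lead murine surface ECGs with known ground truth.

# Raised-cosine bump with compact support exactly `width` ms, so that the
# on-disk P/QRS durations equal the preset values by construction.
# `t` in ms relative to bump onset.
rc_bump <- function(t, width) {
  v <- numeric(length(t))
  inside <- t >= 0 & t <= width
  v[inside] <- 0.5 * (1 - cos(2 * pi * t[inside] / width))
  v
}

# Fragmented (double-peaked) P wave: the same raised-cosine envelope with a
# multiplicative central notch.  The onset/offset edge shape is identical
# to the single-peak morphology, so noise-band fiducial measurement treats
# both morphologies alike; total support is still exactly `width`.
p_wave <- function(t, width, morphology) {
  v <- rc_bump(t, width)
  if (morphology == "double_peak") {
    notch <- rep(1, length(t))
    mid <- t >= width / 3 & t <= 2 * width / 3
    notch[mid] <- 1 - 0.55 * 0.5 * (1 - cos(2 * pi * (t[mid] - width / 3) / (width / 3)))
    v <- v * notch
  }
  v
}

#' Generate a synthetic surface ECG with ground truth
#'
#' Beats are built from parameterized P/QRS/T deflection templates with
#' compact support equal to the preset durations, placed on a beat schedule
#' whose instantaneous heart rate is Gaussian around the preset rate.
#' Premature atrial complexes are inserted as 60%-premature beats with a
#' fully compensatory pause.  Atrial fibrillation episodes replace P waves
#' with a continuous irregular fibrillatory oscillation and draw R-R
#' intervals from a lognormal distribution with the preset coefficient of
#' variation.  Identical `(preset, duration, seed)` calls are
#' bit-identical.
#'
#' @param preset An [ecg_preset()].
#' @param duration Recording length in seconds (>= 1).
#' @param seed Integer seed.
#' @param recording_id,animal_id,day Identifiers forwarded to the
#'   recording.
#'
#' @return A list of class `ecg_sim`:
#' \describe{
#'   \item{ecg}{an [ecg_recording()] (mV).}
#'   \item{truth}{`beats` data frame (`time_s`, `label` in
#'     sinus/PAC/in_AF), `fiducials` (ms relative to R: `p_onset`,
#'     `p_offset`, `qrs_onset`, `qrs_offset`), `af_episodes` data frame
#'     (`start_s`, `end_s`), `af_sample_mask` logical vector.}
#' }
#' @export
generate_ecg <- function(preset, duration, seed, recording_id = NA_character_,
                         animal_id = NA_character_, day = NA_character_) {
  p <- validate_ecg_preset(preset)
  if (!is.numeric(duration) || duration < 1) config_error("duration must be >= 1 s")
  for (ep in p$af_episodes) {
    if (ep[1] + ep[2] > duration) {
      config_error("AF episode [%g s + %g s] extends beyond the %g s recording", ep[1], ep[2], duration)
    }
  }
  fs <- p$sampling_rate
  n <- round(duration * fs)
  m_ms <- 60000 / p$heart_rate

  af <- if (length(p$af_episodes)) {
    do.call(rbind, lapply(p$af_episodes, function(e) data.frame(start_s = e[1], end_s = e[1] + e[2])))
  } else {
    data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  in_af <- function(t_s) any(t_s >= af$start_s & t_s < af$end_s)

  sim <- with_seed(seed, {
    ## Beat schedule ------------------------------------------------------
    t_ms <- 100                          # first beat 0.1 s in
    times <- t_ms
    labels <- if (in_af(t_ms / 1000)) "in_AF" else "sinus"
    sdlog <- sqrt(log(1 + p$rr_irregularity^2))
    repeat {
      if (in_af(t_ms / 1000)) {
        rr <- m_ms * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
        rr <- max(rr, 45)
      } else {
        hr_i <- stats::rnorm(1, p$heart_rate, p$hr_sd)
        rr <- 60000 / max(hr_i, p$heart_rate / 2)
      }
      t_ms <- t_ms + rr
      if (t_ms / 1000 >= duration - 0.02) break
      times <- c(times, t_ms)
      labels <- c(labels, if (in_af(t_ms / 1000)) "in_AF" else "sinus")
    }

    ## Premature atrial complexes ----------------------------------------
    n_pac <- round(p$pac_per_min * duration / 60)
    if (n_pac > 0) {
      eligible <- which(labels == "sinus")
      eligible <- eligible[eligible > 6 & eligible < length(times)]
      eligible <- eligible[labels[eligible - 1L] == "sinus" & labels[eligible + 1L] == "sinus"]
      pick <- integer(0)
      for (cand in sample(eligible)) {
        if (length(pick) >= n_pac) break
        if (all(abs(cand - pick) > 2L)) pick <- c(pick, cand)
      }
      for (i in sort(pick)) {
        # early beat at 60% of the local mean RR, fully compensatory pause
        times[i] <- times[i - 1L] + 0.6 * m_ms
        labels[i] <- "PAC"
        shift <- (times[i - 1L] + 2 * m_ms) - times[i + 1L]
        if (i + 1L <= length(times)) {
          times[(i + 1L):length(times)] <- times[(i + 1L):length(times)] + shift
        }
      }
      keep <- times / 1000 < duration - 0.02
      times <- times[keep]; labels <- labels[keep]
    }

    ## Waveform -----------------------------------------------------------
    t_samp_ms <- (seq_len(n) - 1L) / fs * 1000
    v <- numeric(n)
    qrs_on <- -p$qrs_duration / 2          # ms relative to R
    p_on <- qrs_on - p$pr_interval
    add_bump <- function(v, onset_ms, width_ms, amp, fun) {
      i0 <- max(1L, ceiling(onset_ms / 1000 * fs) + 1L)
      i1 <- min(n, floor((onset_ms + width_ms) / 1000 * fs) + 1L)
      if (i1 < i0) return(v)
      idx <- i0:i1
      v[idx] <- v[idx] + amp * fun(t_samp_ms[idx] - onset_ms, width_ms)
      v
    }
    for (b in seq_along(times)) {
      r <- times[b]
      v <- add_bump(v, r + qrs_on, p$qrs_duration, p$qrs_amplitude, rc_bump)
      v <- add_bump(v, r + p$qrs_duration / 2 + 5, 30, p$t_amplitude, rc_bump)
      if (labels[b] != "in_AF") {
        v <- add_bump(v, r + p_on, p$p_duration, p$p_amplitude,
                      function(t, w) p_wave(t, w, p$p_morphology))
      }
    }

    ## Fibrillatory waves and noise ---------------------------------------
    af_mask <- rep(FALSE, n)
    if (nrow(af)) {
      for (k in seq_len(nrow(af))) {
        af_mask[t_samp_ms / 1000 >= af$start_s[k] & t_samp_ms / 1000 < af$end_s[k]] <- TRUE
      }
      phase <- cumsum(stats::rnorm(n, 0, 0.08))
      fw <- p$f_wave_amplitude * sin(2 * pi * p$f_wave_freq * t_samp_ms / 1000 + phase)
      v[af_mask] <- v[af_mask] + fw[af_mask]
    }
    if (p$noise_sd > 0) v <- v + stats::rnorm(n, 0, p$noise_sd)

    list(v = v, times = times, labels = labels, af_mask = af_mask,
         p_on = p_on, qrs_on = qrs_on)
  })

  ecg <- ecg_recording(sim$v, fs, recording_id = recording_id,
                       animal_id = animal_id, day = day)
  truth <- list(
    beats = data.frame(time_s = sim$times / 1000, label = sim$labels,
                       stringsAsFactors = FALSE),
    fiducials = c(p_onset = sim$p_on, p_offset = sim$p_on + p$p_duration,
                  qrs_onset = sim$qrs_on, qrs_offset = sim$qrs_on + p$qrs_duration),
    af_episodes = af,
    af_sample_mask = sim$af_mask
  )
  structure(list(ecg = ecg, truth = truth, preset = p), class = "ecg_sim")
}
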