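## Generator presets for the control (CON) and atrial AMPK-knockout (dKO)
## phenotypes.  Only the dKO/CON ratios are anchored to reported effect
## sizes; absolute control values are physiological choices for young adult
## C57BL/6 mice (see the methods vignette).

# Effect-size factors encoded once, so dKO presets are derived from CON by
# construction and the ratios are exact.
.effects <- list(
  activation_time_factor = 1.40,   # 40% longer left atrial activation
  upstroke_factor        = 0.50,   # 50% lower upstroke velocity
  apd75_factor           = 1.50,   # ~50% APD75 prolongation
  p_duration_factor      = 2.0,    # 2-fold P-wave duration
  pr_factor              = 1.10,   # 10% PR prolongation
  qrs_factor             = 1.00,   # unchanged QRS
  hr_sd_factor           = 3.0,    # 3-fold SD of heart rate
  pitx2c_la_ra_fold      = 160,    # CON left vs right atrium
  pitx2c_dko_fold        = 0.40,   # dKO vs CON left atrium
  mef2c_la_ra_fold       = 1.75    # CON left vs right atrium
)

#' Optical-mapping generator preset
#'
#' Parameter set for [generate_optical_movie()].  The built-in presets
#' emulate a Langendorff-perfused mouse heart paced from the left atrium at
#' 10 Hz and imaged with an 80 x 80 pixel CCD at 50 um interpixel
#' resolution, stained with a dye whose fluorescence decreases on
#' depolarization: `"CON"` for control hearts and `"dKO"` for atrial
#' AMPK-knockout hearts (1.4x activation time, 0.5x upstroke velocity,
#' 1.5x APD75 relative to control, exactly, by construction).
#'
#' @param name `"CON"` or `"dKO"`.
#' @param ... Overrides for individual fields, e.g. `noise_sd = 0`,
#'   `n_beats = 20`, `simultaneous = TRUE` (infinite conduction velocity:
#'   all pixels activate together).
#'
#' @return An object of class `optical_preset`: a validated list with fields
#'   `grid_size` (pixels), `pixel_pitch` (mm), `frame_interval` (ms),
#'   `pacing_cycle_length` (ms), `n_beats`, `conduction_velocity` (mm/ms),
#'   `upstroke_rise_time` (ms), `apd75_true` (ms), `full_repol_time` (ms),
#'   `ap_amplitude` / `baseline_level` / `noise_sd` (camera counts),
#'   `polarity`, `pacing_site`, `simultaneous`, `lead_in` (ms of diastole
#'   before the first stimulus).
#' @export
#' @examples
#' p <- optical_preset("dKO", noise_sd = 0)
#' p$apd75_true / optical_preset("CON")$apd75_true   # exactly 1.5
optical_preset <- function(name = c("CON", "dKO"), ...) {
  name <- match.arg(name)
  p <- list(
    name = name,
    grid_size = c(80L, 80L),
    pixel_pitch = 0.05,            # mm
    frame_interval = 1.0,          # ms
    pacing_cycle_length = 100,     # ms (10 Hz pacing)
    n_beats = 10L,
    conduction_velocity = 0.5,     # mm/ms: planar wave crosses 4 mm in 8 ms
    upstroke_rise_time = 2,        # ms
    apd75_true = 30,               # ms
    full_repol_time = 72,          # ms from peak back to baseline exactly
    ap_amplitude = 1000,           # counts
    baseline_level = 30000,        # counts
    noise_sd = 20,                 # counts
    polarity = "fluorescence_decreases_on_depolarization",
    pacing_site = c(39.5, -21),    # (row, col): electrode 21 pitches (1.05 mm)
                                   # off the left field edge, so even the
                                   # nearest pixel's upstroke foot starts
                                   # after the stimulus
    simultaneous = FALSE,
    wave_geometry = "planar",      # or "point": concentric fronts from the site
    quantize = TRUE,               # round to integer camera counts
    lead_in = 10                   # ms
  )
  if (name == "dKO") {
    p$conduction_velocity <- p$conduction_velocity / .effects$activation_time_factor
    p$upstroke_rise_time <- p$upstroke_rise_time / .effects$upstroke_factor
    p$apd75_true <- p$apd75_true * .effects$apd75_factor
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) config_error("unknown optical preset field(s): %s", paste(bad, collapse = ", "))
  p[names(over)] <- over
  validate_optical_preset(p)
}

validate_optical_preset <- function(p) {
  fi <- p$frame_interval
  if (fi <= 0 || p$pacing_cycle_length <= 0) config_error("frame_interval and pacing_cycle_length must be positive")
  n_cycle <- p$pacing_cycle_length / fi
  if (abs(n_cycle - round(n_cycle)) > 1e-9) {
    config_error("pacing_cycle_length (%g ms) must be an integer number of frame intervals (%g ms)",
                 p$pacing_cycle_length, fi)
  }
  if (n_cycle < 2 * p$apd75_true / fi) {
    config_error("pacing cycle (%g frames) must be at least twice apd75_true (%g ms) in frames",
                 n_cycle, p$apd75_true)
  }
  if (p$n_beats < 8) config_error("n_beats must be >= 8 (ensemble averaging needs 8 consecutive beats)")
  if (p$conduction_velocity <= 0) config_error("conduction_velocity must be > 0")
  if (!(p$apd75_true > p$upstroke_rise_time) || p$upstroke_rise_time <= 0) {
    config_error("need apd75_true > upstroke_rise_time > 0")
  }
  if (!p$polarity %in% c("fluorescence_decreases_on_depolarization",
                         "fluorescence_increases_on_depolarization")) {
    config_error("unknown polarity '%s'", p$polarity)
  }
  structure(p, class = "optical_preset")
}

#' Surface-ECG generator preset
#'
#' Parameter set for [generate_ecg()].  Built-in presets:
#' \describe{
#'   \item{`"CON"`}{control mouse in sinus rhythm at 500 bpm with minor
#'     physiological heart-rate variability (SD of instantaneous HR 10 bpm).}
#'   \item{`"dKO_wk1"`}{week-1 knockout signature: doubled, double-peaked
#'     (fragmented) P waves, 10% PR prolongation, unchanged QRS.}
#'   \item{`"dKO_wk2_4"`}{week 2-4 knockout signature: adds premature atrial
#'     complexes (60%-premature beats with compensatory pause, 3 per minute)
#'     calibrated so the SD of instantaneous heart rate is ~3x control.}
#'   \item{`"dKO_af"`}{as `"dKO_wk1"` plus one 40 s atrial fibrillation
#'     episode starting at 10 s (override via `af_episodes`).}
#' }
#'
#' @param name Preset name.
#' @param ... Field overrides, e.g. `noise_sd = 0`,
#'   `af_episodes = list(c(start_s = 5, duration_s = 20))`.
#'
#' @return An object of class `ecg_preset` with fields `sampling_rate` (Hz),
#'   `heart_rate` (bpm), `hr_sd` (bpm, sinus SD of instantaneous HR),
#'   `p_duration`, `pr_interval`, `qrs_duration` (ms), `p_morphology`,
#'   `p_amplitude`, `qrs_amplitude`, `t_amplitude`, `f_wave_amplitude` (mV),
#'   `pac_per_min`, `af_episodes`, `rr_irregularity` (CV of RR in AF),
#'   `noise_sd` (mV).
#' @export
ecg_preset <- function(name = c("CON", "dKO_wk1", "dKO_wk2_4", "dKO_af"), ...) {
  name <- match.arg(name)
  p <- list(
    name = name,
    sampling_rate = 2000,          # Hz
    heart_rate = 500,              # bpm
    hr_sd = 10,                    # bpm, sinus beat-to-beat HR jitter
    p_duration = 12,               # ms
    pr_interval = 38,              # ms, P onset to QRS onset
    qrs_duration = 10,             # ms
    p_morphology = "single_peak",
    p_amplitude = 0.15,            # mV
    qrs_amplitude = 1.0,           # mV
    t_amplitude = 0.10,            # mV
    f_wave_amplitude = 0.05,       # mV, fibrillatory waves during AF
    f_wave_freq = 15,              # Hz
    pac_per_min = 0,
    af_episodes = list(),          # list of c(start_s, duration_s)
    rr_irregularity = 0.30,        # CV of RR during AF
    noise_sd = 0.002               # mV (shielded-chamber recording)
  )
  if (name %in% c("dKO_wk1", "dKO_wk2_4", "dKO_af")) {
    p$p_duration <- p$p_duration * .effects$p_duration_factor
    p$pr_interval <- p$pr_interval * .effects$pr_factor
    p$qrs_duration <- p$qrs_duration * .effects$qrs_factor
    p$p_morphology <- "double_peak"
  }
  if (name == "dKO_wk2_4") p$pac_per_min <- 3
  if (name == "dKO_af") p$af_episodes <- list(c(10, 40))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) config_error("unknown ecg preset field(s): %s", paste(bad, collapse = ", "))
  p[names(over)] <- over
  validate_ecg_preset(p)
}

validate_ecg_preset <- function(p) {
  durs <- c(p$p_duration, p$pr_interval, p$qrs_duration)
  if (any(durs <= 0)) config_error("all ECG durations must be positive")
  if (p$pr_interval <= p$p_duration) {
    config_error("pr_interval (%g ms) must exceed p_duration (%g ms)", p$pr_interval, p$p_duration)
  }
  if (p$sampling_rate < 1000) config_error("sampling_rate must be >= 1000 Hz")
  if (p$heart_rate <= 0 || p$hr_sd < 0) config_error("heart_rate must be positive and hr_sd non-negative")
  for (ep in p$af_episodes) {
    if (length(ep) != 2 || any(!is.finite(ep)) || ep[2] <= 0 || ep[1] < 0) {
      config_error("each AF episode must be c(start_s, duration_s) with duration > 0")
    }
  }
  structure(p, class = "ecg_preset")
}

#' qPCR Ct-table generator preset
#'
#' Ground-truth expression design for [generate_ct_table()]: an atrial panel
#' of target genes (`Pitx2c`, `Mef2c`) plus the reference gene `Gapdh`
#' across four groups (`CON_LA`, `CON_RA`, `dKO_LA`, `dKO_RA`).  Encoded
#' fold changes: 160-fold Pitx2c left-vs-right atrium in control, 0.40-fold
#' Pitx2c dKO-vs-CON left atrium, 1.75-fold Mef2c left-vs-right in control;
#' right-atrial expression and the abolished dKO gradients follow the same
#' design (knockout left atrium falls to right-atrial levels for Mef2c).
#'
#' @param ... Overrides: `reference_ct`, `base_ct`, or a replacement
#'   `delta_ct` named matrix (genes x groups of true Ct - reference Ct).
#' @return An object of class `qpcr_preset`.
#' @export
qpcr_preset <- function(...) {
  # True per-group delta-Ct (target Ct minus reference Ct).  A fold of f
  # between groups a and b means dCt_a = dCt_b - log2(f).
  dct <- rbind(
    Pitx2c = c(
      CON_RA = 10,
      CON_LA = 10 - log2(.effects$pitx2c_la_ra_fold),
      dKO_LA = 10 - log2(.effects$pitx2c_la_ra_fold) - log2(.effects$pitx2c_dko_fold),
      dKO_RA = 10
    ),
    Mef2c = c(
      CON_RA = 6,
      CON_LA = 6 - log2(.effects$mef2c_la_ra_fold),
      dKO_LA = 6,
      dKO_RA = 6
    )
  )
  p <- list(
    genes = rownames(dct),
    reference_gene = "Gapdh",
    groups = colnames(dct),
    delta_ct = dct,
    reference_ct = 18,   # raw Ct of the reference gene
    noise_sd = 0.15      # Ct units, replicate-to-replicate
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) config_error("unknown qpcr preset field(s): %s", paste(bad, collapse = ", "))
  p[names(over)] <- over
  structure(p, class = "qpcr_preset")
}

#' @export
print.optical_preset <- function(x, ...) {
  cat(sprintf("<optical_preset %s> %dx%d px @ %g mm, CL %g ms, %d beats\n",
              x$name, x$grid_size[1], x$grid_size[2], x$pixel_pitch,
              x$pacing_cycle_length, x$n_beats))
  cat(sprintf("  CV %.3f mm/ms, rise %g ms, APD75 %g ms, noise %g counts\n",
              x$conduction_velocity, x$upstroke_rise_time, x$apd75_true, x$noise_sd))
  invisible(x)
}

#' @export
print.ecg_preset <- function(x, ...) {
  cat(sprintf("<ecg_preset %s> %g Hz, HR %g bpm, P %g ms (%s), PR %g ms, QRS %g ms\n",
              x$name, x$sampling_rate, x$heart_rate, x$p_duration,
              x$p_morphology, x$pr_interval, x$qrs_duration))
  if (x$pac_per_min > 0) cat(sprintf("  PACs: %g/min\n", x$pac_per_min))
  if (length(x$af_episodes)) {
    cat(sprintf("  AF episodes: %s\n", paste(vapply(
      x$af_episodes, function(e) sprintf("[%gs +%gs]", e[1], e[2]), ""), collapse = " ")))
  }
  invisible(x)
}
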