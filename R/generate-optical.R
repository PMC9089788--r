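## Synthetic optical-mapping movies with known per-pixel ground truth.

# Repolarization time constant for the truncated-exponential recovery:
# g(s) = (exp(-s/tau) - E) / (1 - E), E = exp(-T/tau), solved so that
# g(a) = 1 - level exactly, i.e. the level-recovery point falls `a` ms
# after the peak.  The truncation makes the trace reach baseline exactly at
# s = T, so diastole is a true isoelectric baseline.
solve_repol_tau <- function(a, T_full, level = 0.75) {
  if (a <= 0 || a >= T_full) config_error("need 0 < apd - rise/2 (%g) < full_repol_time (%g)", a, T_full)
  target <- 1 - level
  f <- function(tau) {
    E <- exp(-T_full / tau)
    (exp(-a / tau) - E) / (1 - E) - target
  }
  stats::uniroot(f, lower = 1e-3, upper = 1e4, tol = 1e-12)$root
}

# Normalized action-potential template: phase u in ms relative to the
# pixel's activation (max-upstroke-slope) instant.  Linear upstroke of
# duration `rise` centred on u = 0, truncated-exponential recovery from the
# peak at u = rise/2.
ap_template <- function(u, rise, tau, T_full) {
  E <- exp(-T_full / tau)
  v <- numeric(length(u))
  ramp <- u >= -rise / 2 & u <= rise / 2
  v[ramp] <- (u[ramp] + rise / 2) / rise
  rec <- u > rise / 2 & u <= rise / 2 + T_full
  s <- u[rec] - rise / 2
  v[rec] <- (exp(-s / tau) - E) / (1 - E)
  v
}

#' Generate a synthetic voltage-dye movie with ground truth
#'
#' Emulates steady-state left-atrial pacing of a perfused mouse heart: a
#' planar wave sweeps the field from the pacing electrode, every pixel fires
#' the same normalized action-potential template (linear upstroke,
#' truncated-exponential repolarization parameterized directly by the
#' 75%-recovery time, so `apd75_true` is exact by construction), identical
#' beats repeat every pacing cycle, dye polarity is applied, and i.i.d.
#' Gaussian camera noise is added before quantization to integer counts.
#'
#' @param preset An [optical_preset()].
#' @param seed Integer seed; identical `(preset, seed)` calls are
#'   bit-identical.
#'
#' @return A list of class `optical_sim`:
#' \describe{
#'   \item{movie}{a [voltage_movie()] (counts, `rows x cols x time`).}
#'   \item{truth}{per-pixel ground-truth matrices `t_act` (ms from
#'     stimulus), `apd75` (ms), `max_slope` (1/ms on the normalized trace),
#'     plus `tau` and `peak_offset` (ms from activation to peak).}
#' }
#' @export
#' @examples
#' sim <- generate_optical_movie(optical_preset("CON", n_beats = 8), seed = 1)
#' range(sim$truth$t_act)
generate_optical_movie <- function(preset, seed) {
  p <- validate_optical_preset(preset)
  nr <- p$grid_size[1]; nc <- p$grid_size[2]
  fi <- p$frame_interval
  cl <- p$pacing_cycle_length
  rise <- p$upstroke_rise_time

  # Ground-truth activation: planar wavefront travelling in +x from the
  # pacing electrode column; pixel column j (0-based) sits (j - site_col)
  # pixel pitches from the electrode.
  cols0 <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  rows0 <- matrix(rep(0:(nr - 1), nc), nr, nc)
  t_act <- if (isTRUE(p$simultaneous)) {
    # equal everywhere; a small latency keeps the upstroke foot inside the
    # stimulus-aligned analysis window
    matrix(2 + p$upstroke_rise_time / 2, nr, nc)
  } else if (identical(p$wave_geometry, "point")) {
    # concentric fronts radiating from the electrode
    sqrt((rows0 - p$pacing_site[1])^2 + (cols0 - p$pacing_site[2])^2) *
      p$pixel_pitch / p$conduction_velocity
  } else {
    (cols0 - p$pacing_site[2]) * p$pixel_pitch / p$conduction_velocity
  }

  a <- p$apd75_true - rise / 2          # peak-to-75%-recovery time
  tau <- solve_repol_tau(a, p$full_repol_time)

  # One-cycle template per pixel (identical beats), evaluated on the phase
  # grid relative to the stimulus.
  phases <- seq(0, cl - fi, by = fi)
  u <- outer(-as.vector(t_act), phases, `+`)           # npx x ncycle
  cyc <- ap_template(as.vector(u), rise, tau, p$full_repol_time)
  dim(cyc) <- dim(u)

  n_lead <- round(p$lead_in / fi)
  n_cycle <- length(phases)
  n_frames <- n_lead + p$n_beats * n_cycle
  npx <- nr * nc

  sig <- matrix(0, npx, n_frames)
  if (n_lead > 0) sig[, seq_len(n_lead)] <- 0
  for (b in seq_len(p$n_beats)) {
    sig[, n_lead + (b - 1L) * n_cycle + seq_len(n_cycle)] <- cyc
  }

  sgn <- if (p$polarity == "fluorescence_decreases_on_depolarization") -1 else 1
  counts <- p$baseline_level + sgn * p$ap_amplitude * sig
  if (p$noise_sd > 0) {
    counts <- counts + with_seed(seed, matrix(stats::rnorm(length(counts), sd = p$noise_sd),
                                              nrow(counts), ncol(counts)))
  }
  if (isTRUE(p$quantize)) counts <- pmin(pmax(round(counts), 0), 65535)
  frames <- array(counts, dim = c(nr, nc, n_frames))

  movie <- voltage_movie(
    frames = frames, frame_interval = fi, pixel_pitch = p$pixel_pitch,
    stimulus_times = p$lead_in + (seq_len(p$n_beats) - 1L) * cl,
    polarity = p$polarity,
    roi = matrix(TRUE, nr, nc)
  )
  truth <- list(
    t_act = t_act,
    apd75 = matrix(p$apd75_true, nr, nc),
    max_slope = matrix(1 / rise, nr, nc),
    tau = tau,
    peak_offset = rise / 2
  )
  structure(list(movie = movie, truth = truth, preset = p), class = "optical_sim")
}
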