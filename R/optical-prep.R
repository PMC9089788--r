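## Raw movie -> one clean normalized beat per pixel.
## Fixed processing order: segment -> ensemble average -> spatial smooth ->
## normalize/baseline-subtract/invert.

#' Ensemble-processing configuration
#'
#' @param n_beats_to_average Number of consecutive beats averaged (default 8).
#' @param smoothing_kernel Side of the uniform spatial kernel in pixels;
#'   odd, >= 1 (default 5).
#' @param baseline_window ms of diastole immediately before the stimulus
#'   used for baseline estimation (default 10).
#' @param amplitude_k ROI pruning threshold: pixels whose peak-to-baseline
#'   amplitude is below `amplitude_k` times the baseline-window noise SD are
#'   dropped from the ROI (default 5).
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_beats_to_average = 8L, smoothing_kernel = 5L,
                            baseline_window = 10, amplitude_k = 5) {
  if (!is_count(smoothing_kernel) || smoothing_kernel < 1 || smoothing_kernel %% 2 == 0) {
    config_error("smoothing_kernel must be an odd positive integer")
  }
  if (!is_count(n_beats_to_average) || n_beats_to_average < 1) {
    config_error("n_beats_to_average must be a positive integer")
  }
  if (baseline_window <= 0) config_error("baseline_window must be positive")
  structure(list(
    n_beats_to_average = as.integer(n_beats_to_average),
    smoothing_kernel = as.integer(smoothing_kernel),
    baseline_window = baseline_window,
    amplitude_k = amplitude_k,
    edge_mode = "reflect"
  ), class = "ensemble_config")
}

#' Segment a paced movie into beat windows
#'
#' One window of one pacing cycle length per stimulus, aligned to the
#' stimulus sample; only windows fully contained in the recording are kept.
#' If the movie carries no stimulus annotations the pacing train is
#' recovered from upstrokes of the global mean trace (requires at least 3
#' periodic deflections).
#'
#' @param movie A [voltage_movie()].
#' @param config An [ensemble_config()]; segmentation fails with an
#'   `atriakit_insufficient_beats` error when fewer complete windows than
#'   `n_beats_to_average` exist.
#' @return A list with `starts` (1-based start frame of each complete
#'   window), `length` (frames per cycle) and `cycle_ms`.
#' @export
segment_beats <- function(movie, config = ensemble_config()) {
  fi <- movie$frame_interval
  n_frames <- dim(movie$frames)[3]
  st <- movie$stimulus_times
  if (!length(st)) st <- detect_stimuli(movie)
  if (length(st) < 2L) {
    stop_atriakit("atriakit_insufficient_beats", "need at least 2 stimuli to define a pacing cycle")
  }
  cycle_ms <- stats::median(diff(st))
  len <- round(cycle_ms / fi)
  starts <- round(st / fi) + 1L
  starts <- starts[starts + len - 1L <= n_frames]
  if (length(starts) < config$n_beats_to_average) {
    stop_atriakit("atriakit_insufficient_beats",
                  "only %d complete beat windows, need %d", length(starts), config$n_beats_to_average)
  }
  list(starts = starts, length = len, cycle_ms = len * fi)
}

# Stimulus recovery from the global mean trace: depolarization-going
# deflections found as threshold crossings of the normalized mean trace.
detect_stimuli <- function(movie) {
  mu <- apply(movie$frames, 3, mean)
  if (movie$polarity == "fluorescence_decreases_on_depolarization") mu <- -mu
  mu <- (mu - stats::quantile(mu, 0.05)) / max(stats::quantile(mu, 0.95) - stats::quantile(mu, 0.05), 1e-12)
  up <- which(diff(mu > 0.5) == 1L)
  if (length(up) < 3L) {
    stop_atriakit("atriakit_insufficient_beats",
                  "no stimulus annotations and fewer than 3 detectable deflections")
  }
  # back up from the half-amplitude crossing to the foot of the upstroke
  (up - 1L) * movie$frame_interval
}

#' Ensemble-average beat windows
#'
#' Pointwise mean of the first `n_beats_to_average` complete windows
#' ("consecutive beats"); output is one cycle long.
#'
#' @param movie A [voltage_movie()].
#' @param windows Output of [segment_beats()].
#' @param config An [ensemble_config()].
#' @return Numeric array `rows x cols x cycle_frames`, with attribute
#'   `frame_interval`.
#' @export
ensemble_average <- function(movie, windows, config = ensemble_config()) {
  n <- config$n_beats_to_average
  if (length(windows$starts) < n) {
    stop_atriakit("atriakit_insufficient_beats",
                  "only %d complete beat windows, need %d", length(windows$starts), n)
  }
  d <- dim(movie$frames)
  acc <- array(0, c(d[1], d[2], windows$length))
  for (s in windows$starts[seq_len(n)]) {
    acc <- acc + movie$frames[, , s:(s + windows$length - 1L), drop = FALSE]
  }
  out <- acc / n
  attr(out, "frame_interval") <- movie$frame_interval
  out
}

# Reflect-padded index vector for a length-n axis and kernel offset k.
reflect_idx <- function(n, k) {
  i <- seq_len(n) + k
  i[i < 1L] <- 2L - i[i < 1L]
  i[i > n] <- 2L * n - i[i > n]
  i
}

#' Spatially smooth an averaged beat stack
#'
#' Per-frame uniform-mean filter (default 5 x 5) with reflect padding at the
#' frame borders.  Pixels outside the ROI are excluded from both input and
#' output: the mean at an ROI pixel is taken over its in-ROI neighbors only
#' (NaN-aware), and non-ROI pixels come out as NaN.
#'
#' @param stack `rows x cols x frames` array (e.g. from
#'   [ensemble_average()]).
#' @param config An [ensemble_config()].
#' @param roi Logical matrix; defaults to all pixels.
#' @return Smoothed array of the same shape.
#' @export
spatial_smooth <- function(stack, config = ensemble_config(), roi = NULL) {
  d <- dim(stack)
  k <- config$smoothing_kernel
  if (k > d[1] || k > d[2]) config_error("smoothing kernel (%d) larger than frame (%dx%d)", k, d[1], d[2])
  if (is.null(roi)) roi <- matrix(TRUE, d[1], d[2])
  if (k == 1L) {
    out <- stack
    out[array(!roi, d)] <- NaN
    return(out)
  }
  half <- (k - 1L) %/% 2L
  w <- matrix(as.numeric(roi), d[1], d[2])
  x <- stack
  x[array(!roi, d)] <- 0
  num <- array(0, d)
  den <- matrix(0, d[1], d[2])
  for (dr in -half:half) {
    ri <- reflect_idx(d[1], dr)
    for (dc in -half:half) {
      ci <- reflect_idx(d[2], dc)
      num <- num + x[ri, ci, , drop = FALSE]
      den <- den + w[ri, ci]
    }
  }
  den[den == 0] <- NaN
  out <- num / array(rep(den, d[3]), d)
  out[array(!roi, d)] <- NaN
  attr(out, "frame_interval") <- attr(stack, "frame_interval")
  out
}

#' Normalize, baseline-subtract and invert a beat stack
#'
#' Per pixel: the trace is inverted if the dye's fluorescence decreases on
#' depolarization, the baseline is the mean over the last `baseline_window`
#' ms before the stimulus (the tail of the cycle), the amplitude is peak
#' minus baseline, and the normalized trace is `(signal - baseline) /
#' amplitude` so it rests at 0 and peaks at exactly 1.  Pixels whose
#' amplitude does not exceed `amplitude_k` times the baseline-window noise
#' SD (flat or signal-free pixels) are dropped from the ROI.
#'
#' @param stack Smoothed one-cycle array from [spatial_smooth()].
#' @param polarity Dye polarity string from the movie metadata.
#' @param config An [ensemble_config()].
#' @param roi Logical matrix; defaults to all finite pixels.
#' @return An object of class `normalized_beat`: `traces`
#'   (`rows x cols x frames`, NaN outside the ROI), `frame_interval` (ms),
#'   `roi`, `amplitude_map` (counts), `baseline_map` (counts).
#' @export
normalize_invert <- function(stack, polarity, config = ensemble_config(), roi = NULL) {
  d <- dim(stack)
  fi <- attr(stack, "frame_interval")
  if (is.null(fi)) config_error("stack has no frame_interval attribute; run the chain in order")
  nb <- round(config$baseline_window / fi)
  if (nb < 1 || nb >= d[3]) config_error("baseline window (%g ms) must fit inside the cycle", config$baseline_window)
  if (is.null(roi)) roi <- apply(is.finite(stack), c(1, 2), all)

  x <- matrix(stack, d[1] * d[2], d[3])
  if (polarity == "fluorescence_decreases_on_depolarization") x <- -x
  bl_cols <- (d[3] - nb + 1L):d[3]
  baseline <- rowMeans(x[, bl_cols, drop = FALSE])
  noise_sd <- apply(x[, bl_cols, drop = FALSE], 1, stats::sd)
  amp <- apply(x, 1, max) - baseline
  keep <- as.vector(roi) & is.finite(amp) & amp > pmax(config$amplitude_k * noise_sd, 0)
  if (!any(keep)) {
    stop_atriakit("atriakit_no_signal", "no pixels left in ROI after amplitude filtering")
  }
  tr <- (x - baseline) / amp
  tr[!keep, ] <- NaN
  traces <- array(tr, d)
  attr(traces, "frame_interval") <- fi
  structure(list(
    traces = traces,
    frame_interval = fi,
    roi = matrix(keep, d[1], d[2]),
    amplitude_map = matrix(ifelse(keep, amp, NaN), d[1], d[2]),
    baseline_map = matrix(ifelse(keep, baseline, NaN), d[1], d[2])
  ), class = "normalized_beat")
}

#' @export
print.normalized_beat <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf("<normalized_beat> %dx%d px, %d frames @ %g ms, ROI %d px\n",
              d[1], d[2], d[3], x$frame_interval, sum(x$roi)))
  invisible(x)
}

#' Full movie-to-beat preparation chain
#'
#' Convenience wrapper running [segment_beats()], [ensemble_average()],
#' [spatial_smooth()] and [normalize_invert()] in the fixed order.
#'
#' @param movie A [voltage_movie()].
#' @param config An [ensemble_config()].
#' @return A `normalized_beat`.
#' @export
prepare_beat <- function(movie, config = ensemble_config()) {
  w <- segment_beats(movie, config)
  avg <- ensemble_average(movie, w, config)
  sm <- spatial_smooth(avg, config, roi = movie$roi)
  normalize_invert(sm, movie$polarity, config, roi = movie$roi)
}
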