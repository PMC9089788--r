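## Core data containers shared across the pipeline.

#' Voltage-dye movie container
#'
#' A time-ordered stack of camera frames with the physical metadata and
#' pacing annotations needed downstream.  Frames are stored as an
#' `rows x cols x time` array of camera counts.
#'
#' @param frames Numeric array, `rows x cols x n_frames` (counts).
#' @param frame_interval Frame interval in ms.
#' @param pixel_pitch Interpixel spacing in mm.
#' @param stimulus_times Pacing stimulus times in ms from the first frame,
#'   strictly increasing, within the recording span.
#' @param polarity `"fluorescence_decreases_on_depolarization"` or
#'   `"fluorescence_increases_on_depolarization"`.
#' @param roi Logical matrix, `rows x cols`; `TRUE` marks tissue pixels.
#'
#' @return An object of class `voltage_movie`.
#' @export
voltage_movie <- function(frames, frame_interval, pixel_pitch, stimulus_times,
                          polarity = "fluorescence_decreases_on_depolarization",
                          roi = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    format_error("frames must be a rows x cols x time array")
  }
  if (dim(frames)[3] < 2L) format_error("a movie needs at least 2 frames")
  if (!is.numeric(frame_interval) || frame_interval <= 0) format_error("frame_interval must be positive")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0) format_error("pixel_pitch must be positive")
  span <- dim(frames)[3] * frame_interval
  st <- as.numeric(stimulus_times)
  if (length(st) && (any(diff(st) <= 0) || any(st < 0) || any(st >= span))) {
    format_error("stimulus_times must be strictly increasing and within the recording span [0, %g ms)", span)
  }
  if (is.null(roi)) roi <- matrix(TRUE, dim(frames)[1], dim(frames)[2])
  if (!identical(dim(roi), dim(frames)[1:2])) {
    format_error("roi mask shape (%s) does not match frame shape (%s)",
                 paste(dim(roi), collapse = "x"), paste(dim(frames)[1:2], collapse = "x"))
  }
  structure(list(
    frames = frames, frame_interval = frame_interval, pixel_pitch = pixel_pitch,
    stimulus_times = st, polarity = polarity, roi = roi == TRUE
  ), class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<voltage_movie> %dx%d px, %d frames @ %g ms (%g ms), pitch %g mm\n",
              d[1], d[2], d[3], x$frame_interval, d[3] * x$frame_interval, x$pixel_pitch))
  cat(sprintf("  %d stimuli, polarity: %s, ROI: %d/%d px\n",
              length(x$stimulus_times), x$polarity, sum(x$roi), d[1] * d[2]))
  invisible(x)
}

#' Single-lead ECG recording container
#'
#' @param samples Numeric vector of voltages (mV), uniformly sampled.
#' @param sampling_rate Sampling rate in Hz.
#' @param recording_id,animal_id,day Optional identifiers used by the
#'   rhythm module's per-day diagnosis rule.
#'
#' @return An object of class `ecg_recording` with `duration` in seconds.
#' @export
ecg_recording <- function(samples, sampling_rate, recording_id = NA_character_,
                          animal_id = NA_character_, day = NA_character_) {
  if (!is.numeric(samples) || length(samples) < 2L) format_error("samples must be a numeric vector")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) format_error("sampling_rate must be positive")
  structure(list(
    samples = as.numeric(samples), sampling_rate = sampling_rate,
    duration = length(samples) / sampling_rate,
    recording_id = recording_id, animal_id = animal_id, day = day
  ), class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording%s> %.1f s @ %g Hz (%d samples)\n",
              if (is.na(x$recording_id)) "" else paste0(" ", x$recording_id),
              x$duration, x$sampling_rate, length(x$samples)))
  invisible(x)
}
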