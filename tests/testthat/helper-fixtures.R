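# Small fixtures shared across test files.  All data are generated in code;
# small grids / short recordings keep the default run fast.

# Compact optical preset: full temporal structure on a small field.
small_optical <- function(name = "CON", ...) {
  optical_preset(name, grid_size = c(12L, 20L), n_beats = 8L, ...)
}

# Hand-built normalized_beat around a single trace, for analytic map
# oracles (these are constructed traces, not movies, so the frame interval
# can be chosen freely).
beat_from_trace <- function(trace, fi = 1) {
  traces <- array(trace, c(1, 1, length(trace)))
  attr(traces, "frame_interval") <- fi
  structure(list(
    traces = traces, frame_interval = fi,
    roi = matrix(TRUE, 1, 1),
    amplitude_map = matrix(1, 1, 1),
    baseline_map = matrix(0, 1, 1)
  ), class = "normalized_beat")
}

# Beat table from a vector of R-R intervals (ms).
beats_from_rr <- function(rr_ms, t0 = 0.1) {
  beat_table(c(t0, t0 + cumsum(rr_ms) / 1000))
}
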