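## On-disk formats: multi-page TIFF movies, PNG masks, CSV traces/maps/
## tables, JSON sidecars.  Conventions: optical times in ms, ECG times in
## seconds, all map units ms; NaN is the only undefined-value sentinel;
## pixel indices in CSV exports are 0-based, row-major, origin top-left.

required_keys <- function(meta, keys, where) {
  for (k in keys) {
    if (is.null(meta[[k]])) format_error("sidecar %s is missing required key '%s'", where, k)
  }
}

#' Write / read a voltage movie (multi-page 16-bit TIFF + JSON sidecar)
#'
#' Frames are stored as 16-bit grayscale pages in time order; metadata
#' (`frame_interval_ms`, `pixel_pitch_mm`, `stimulus_times_ms`, `polarity`,
#' `roi_mask_path`) goes to a JSON sidecar and the ROI to an 8-bit PNG.
#' Counts must lie in 0..65535; the write->read round trip is bit-exact for
#' integer counts.
#'
#' @param movie A [voltage_movie()].
#' @param tiff_path Output TIFF path.
#' @param sidecar_path JSON sidecar path (default: `tiff_path` + `.json`).
#' @param roi_path ROI PNG path (default: `tiff_path` + `_roi.png`).
#' @return `tiff_path`, invisibly.
#' @export
write_movie <- function(movie, tiff_path, sidecar_path = NULL, roi_path = NULL) {
  sidecar_path <- sidecar_path %||% paste0(tiff_path, ".json")
  roi_path <- roi_path %||% paste0(tiff_path, "_roi.png")
  d <- dim(movie$frames)
  if (min(movie$frames) < 0 || max(movie$frames) > 65535) {
    format_error("frame counts must lie in [0, 65535] for 16-bit storage")
  }
  pages <- lapply(seq_len(d[3]), function(i) movie$frames[, , i] / 65535)
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 16, compression = "none")
  png::writePNG(matrix(as.numeric(movie$roi), d[1], d[2]), roi_path)
  jsonlite::write_json(list(
    frame_interval_ms = movie$frame_interval,
    pixel_pitch_mm = movie$pixel_pitch,
    stimulus_times_ms = as.numeric(movie$stimulus_times),
    polarity = movie$polarity,
    roi_mask_path = basename(roi_path),
    rows = d[1], cols = d[2], n_frames = d[3]
  ), sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_movie
#' @return For `read_movie`, a validated [voltage_movie()]; a missing ROI
#'   mask falls back to a full-frame mask with a warning, while a missing
#'   metadata key or a shape mismatch is a format error naming the
#'   offender.
#' @export
read_movie <- function(tiff_path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||% paste0(tiff_path, ".json")
  if (!file.exists(tiff_path)) format_error("movie file '%s' does not exist", tiff_path)
  if (!file.exists(sidecar_path)) format_error("sidecar '%s' does not exist", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required_keys(meta, c("frame_interval_ms", "pixel_pitch_mm", "stimulus_times_ms", "polarity"),
                sidecar_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]])[1:2], length(pages))
  frames <- array(vapply(pages, function(p) round(p * 65535), matrix(0, d[1], d[2])), d)
  roi <- NULL
  if (!is.null(meta$roi_mask_path)) {
    rp <- file.path(dirname(tiff_path), meta$roi_mask_path)
    if (file.exists(rp)) {
      roi <- png::readPNG(rp)
      if (length(dim(roi)) == 3L) roi <- roi[, , 1]
      roi <- roi > 0.5
    }
  }
  if (is.null(roi)) {
    warning("no ROI mask found; using a full-frame mask")
    roi <- matrix(TRUE, d[1], d[2])
  }
  voltage_movie(frames, meta$frame_interval_ms, meta$pixel_pitch_mm,
                meta$stimulus_times_ms, meta$polarity, roi)
}

#' Write / read an ECG recording (CSV trace + JSON sidecar)
#'
#' Comma-separated, header row `time_s,voltage_mV`, '.' decimal; the
#' sidecar carries `sampling_rate_hz`, `lead` and identifiers.
#'
#' @param ecg An [ecg_recording()].
#' @param csv_path Trace CSV path.
#' @param sidecar_path JSON sidecar path (default: `csv_path` + `.json`).
#' @param lead Lead label stored in the sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_ecg <- function(ecg, csv_path, sidecar_path = NULL, lead = "II") {
  sidecar_path <- sidecar_path %||% paste0(csv_path, ".json")
  t_s <- (seq_along(ecg$samples) - 1L) / ecg$sampling_rate
  utils::write.csv(data.frame(time_s = t_s, voltage_mV = ecg$samples),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    sampling_rate_hz = ecg$sampling_rate, lead = lead,
    recording_id = ecg$recording_id, animal_id = ecg$animal_id, day = ecg$day
  ), sidecar_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(csv_path)
}

#' @rdname write_ecg
#' @return For `read_ecg`, an [ecg_recording()]; a non-uniform time column
#'   (tolerance 1e-6 s) or an empty CSV is a format error.
#' @export
read_ecg <- function(csv_path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||% paste0(csv_path, ".json")
  if (!file.exists(csv_path)) format_error("ECG file '%s' does not exist", csv_path)
  df <- utils::read.csv(csv_path)
  if (!nrow(df)) format_error("ECG CSV '%s' is empty", csv_path)
  required_keys(as.list(df[1, ]), c("time_s", "voltage_mV"), csv_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required_keys(meta, "sampling_rate_hz", sidecar_path)
  fs <- meta$sampling_rate_hz
  if (nrow(df) > 1 && max(abs(diff(df$time_s) - 1 / fs)) > 1e-6) {
    format_error("time column of '%s' is not uniform at %g Hz (tolerance 1e-6 s)", csv_path, fs)
  }
  ecg_recording(df$voltage_mV, fs,
                recording_id = meta$recording_id %||% NA_character_,
                animal_id = meta$animal_id %||% NA_character_,
                day = meta$day %||% NA_character_)
}

#' Write / read a scalar pixel map
#'
#' The canonical on-disk form is a CSV grid (one row per pixel row, `NaN`
#' for undefined pixels).  When `tiff_path` is given, a 32-bit float TIFF
#' companion is written as two pages - finite values affinely rescaled to
#' \code{[0, 1]} plus a validity mask - with the affine transform recorded in a
#' JSON sidecar, because float TIFF storage here is defined only on
#' \code{[0, 1]} and has no NaN representation.
#'
#' @param m Numeric matrix (ms), NaN for undefined pixels, or one of the
#'   map objects (`activation_map`, `apd_map`, `upstroke_map`).
#' @param csv_path Output CSV path.
#' @param tiff_path Optional TIFF companion path.
#' @return `csv_path`, invisibly.
#' @export
write_map <- function(m, csv_path, tiff_path = NULL) {
  if (inherits(m, "activation_map")) m <- m$t_act
  if (inherits(m, "apd_map")) m <- m$apd
  if (inherits(m, "upstroke_map")) m <- m$max_slope
  if (!is.matrix(m)) format_error("map must be a numeric matrix")
  utils::write.table(m, csv_path, sep = ",", row.names = FALSE, col.names = FALSE)
  if (!is.null(tiff_path)) {
    fin <- is.finite(m)
    offset <- if (any(fin)) min(m[fin]) else 0
    scale <- if (any(fin)) max(max(m[fin]) - offset, 1e-12) else 1
    page <- matrix(0, nrow(m), ncol(m))
    page[fin] <- (m[fin] - offset) / scale
    tiff::writeTIFF(list(page, matrix(as.numeric(fin), nrow(m), ncol(m))),
                    tiff_path, bits.per.sample = 32)
    jsonlite::write_json(list(offset = offset, scale = scale),
                         paste0(tiff_path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' @rdname write_map
#' @param source `"csv"` or `"tiff"`: which representation to read.
#' @param path Path to the CSV grid or TIFF written by [write_map()].
#' @return For `read_map`, the numeric matrix with NaN for undefined
#'   pixels.
#' @export
read_map <- function(path, source = c("csv", "tiff")) {
  source <- match.arg(source)
  if (!file.exists(path)) format_error("map file '%s' does not exist", path)
  if (source == "csv") {
    m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    mode(m) <- "numeric"
    m[is.na(m)] <- NaN              # undefined pixels are NaN, never NA
    return(m)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- pages[[1]] * meta$scale + meta$offset
  m[pages[[2]] < 0.5] <- NaN
  m
}

#' Write / read a plain CSV table
#'
#' @param rows A data frame.
#' @param path CSV path.
#' @return `path` invisibly; `read_table_csv` returns the data frame.
#' @export
write_table_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) format_error("table '%s' does not exist", path)
  df <- utils::read.csv(path)
  if (!nrow(df)) format_error("table '%s' is empty", path)
  df
}

#' Run manifest
#'
#' Writes a JSON manifest (inputs, configuration, seed, package version)
#' sufficient to reproduce a deterministic pipeline stage bit-for-bit.
#'
#' @param path Output JSON path.
#' @param inputs Named list or character vector of input descriptions.
#' @param config Configuration list.
#' @param seed Seed used (or NULL).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = list(), config = list(), seed = NULL) {
  jsonlite::write_json(list(
    package = "atriakit",
    version = tryCatch(as.character(utils::packageVersion("atriakit")),
                       error = function(e) NA_character_),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = inputs,
    config = config
  ), path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
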