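#' A single segmented vocalization
#'
#' The atomic record of the pipeline: one call's waveform with its sample
#' rate and, when known, a call-type label. Amplitudes are dimensionless and
#' nominally within \[-1, 1\]; the corpus default rate is 44.1 kHz.
#'
#' @param samples Numeric vector of amplitudes (non-empty, all finite).
#' @param rate Sample rate in samples/second (> 0). Default 44100.
#' @param label Optional call-type name.
#' @param source_id Provenance string (file path, generator id, ...).
#' @return An object of class `call_recording`.
#' @export
call_recording <- function(samples, rate = 44100, label = NULL,
                           source_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("`samples` must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) stop("`samples` must be finite", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = as.numeric(rate),
         label = if (is.null(label)) NULL else as.character(label),
         source_id = as.character(source_id)),
    class = "call_recording"
  )
}

#' @rdname call_recording
#' @param x Object to test.
#' @export
is_call_recording <- function(x) inherits(x, "call_recording")

#' @export
print.call_recording <- function(x, ...) {
  cat(sprintf("<call_recording> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (!is.null(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' Band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero-phase), the standard pre-processing for this corpus: recordings
#' were filtered to the 4-10 kHz band in which marmoset calls carry their
#' energy, so segmentation thresholds respond to calls rather than to cage
#' noise.
#'
#' @param recording A [call_recording()].
#' @param low_hz,high_hz Passband edges in Hz; defaults 4000 and 10000.
#'   Must satisfy `0 < low_hz < high_hz < rate / 2`.
#' @return A [call_recording()] of the same length.
#' @export
bandpass_filter <- function(recording, low_hz = 4000, high_hz = 10000) {
  stopifnot(is_call_recording(recording))
  nyq <- recording$rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("invalid band: need 0 < low_hz < high_hz < rate/2 (Nyquist = ",
         nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  filtered <- signal::filtfilt(bf, recording$samples)
  call_recording(filtered, rate = recording$rate, label = recording$label,
                 source_id = recording$source_id)
}

#' Threshold-segment a continuous signal into call candidates
#'
#' Implements the corpus segmentation rule: a call candidate spans from
#' `pad_s` seconds before its first amplitude-threshold crossing to `pad_s`
#' seconds after its last, clipped to the signal bounds. Crossings whose
#' padded spans overlap belong to one event and are merged, so bursts closer
#' than `2 * pad_s` become a single segment.
#'
#' @param samples Numeric amplitude vector (a [call_recording()] is also
#'   accepted).
#' @param rate Sample rate in Hz (ignored when `samples` is a recording).
#' @param threshold Positive amplitude threshold. `NULL` (default) uses
#'   `5 * median(abs(samples))`, a noise-floor-robust automatic choice.
#' @param pad_s Padding in seconds on each side of an event; default 0.5.
#' @return A tibble with columns `start_s`, `end_s`, ordered by start time;
#'   zero rows when nothing crosses the threshold.
#' @export
segment_signal <- function(samples, rate = 44100, threshold = NULL,
                           pad_s = 0.5) {
  if (is_call_recording(samples)) {
    rate <- samples$rate
    samples <- samples$samples
  }
  if (length(samples) == 0L) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  if (is.null(threshold)) threshold <- 5 * stats::median(abs(samples))
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive", call. = FALSE)
  }
  if (pad_s < 0) stop("`pad_s` must be non-negative", call. = FALSE)

  above <- which(abs(samples) > threshold)
  if (length(above) == 0L) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  t_cross <- (above - 1L) / rate
  start <- t_cross - pad_s
  end <- t_cross + pad_s

  # merge crossings whose padded spans overlap or touch
  new_event <- c(TRUE, start[-1L] > cummax_head(end))
  event_id <- cumsum(new_event)
  dur <- (length(samples) - 1L) / rate
  tibble::tibble(
    start_s = pmax(0, tapply(start, event_id, min)),
    end_s = pmin(dur, tapply(end, event_id, max))
  )
}

# running max of the previous elements (end[i-1] ... ), used for merge test
cummax_head <- function(x) cummax(x)[-length(x)]

#' Extract segment waveforms from a recording
#'
#' @param recording A [call_recording()].
#' @param segments A tibble with `start_s`/`end_s` columns, as produced by
#'   [segment_signal()].
#' @return A list of [call_recording()]s, one per segment, inheriting the
#'   parent's label and source id.
#' @export
extract_segments <- function(recording, segments) {
  stopifnot(is_call_recording(recording))
  purrr::pmap(segments, function(start_s, end_s, ...) {
    i0 <- max(1L, floor(start_s * recording$rate) + 1L)
    i1 <- min(length(recording$samples), ceiling(end_s * recording$rate) + 1L)
    call_recording(recording$samples[i0:i1], rate = recording$rate,
                   label = recording$label, source_id = recording$source_id)
  })
}

#' Load a labeled call dataset from a CSV manifest
#'
#' The manifest has columns `file` (WAV path, relative to `audio_root`) and
#' `label` (call-type name). One recording is returned per row.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param audio_root Directory that `file` entries are relative to; defaults
#'   to the manifest's directory.
#' @param corpus_rate Expected sample rate; mismatching files trigger a
#'   warning (they are still loaded at their native rate).
#' @param classes Optional fixed vector of allowed labels; any other label
#'   is an error.
#' @return A tibble with columns `file`, `label`, `rate`, `duration_s` and a
#'   list-column `recording` of [call_recording()]s.
#' @export
load_dataset <- function(manifest_path, audio_root = dirname(manifest_path),
                         corpus_rate = 44100, classes = NULL) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("file", "label") %in% names(manifest))) {
    stop("manifest must have columns `file` and `label`", call. = FALSE)
  }
  if (nrow(manifest) == 0L) {
    return(tibble::tibble(file = character(), label = character(),
                          rate = numeric(), duration_s = numeric(),
                          recording = list()))
  }
  if (!is.null(classes)) {
    bad <- setdiff(unique(manifest$label), classes)
    if (length(bad) > 0L) {
      stop("unknown label(s) in manifest: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  recs <- purrr::map2(manifest$file, manifest$label, function(f, lab) {
    read_wav(file.path(audio_root, f), label = lab)
  })
  rates <- purrr::map_dbl(recs, "rate")
  if (any(rates != corpus_rate)) {
    warning(sum(rates != corpus_rate), " file(s) deviate from the corpus ",
            "rate of ", corpus_rate, " Hz")
  }
  tibble::tibble(
    file = manifest$file,
    label = manifest$label,
    rate = rates,
    duration_s = purrr::map_dbl(recs, ~ length(.x$samples) / .x$rate),
    recording = recs
  )
}
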