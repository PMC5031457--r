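#' The synthetic call-archetype table
#'
#' Deterministic stand-ins for the 11 marmoset call types, parameterized by
#' spectral shape in the 4-10 kHz analysis band. Tonal archetypes are
#' frequency-modulated sinusoids (optionally with a linear up-sweep per
#' syllable); broadband archetypes are band-limited noise bursts; the
#' `mixed` profile (Tsik-ek) is a broadband chevron followed by a tonal
#' harmonic tail at 0.6 x carrier. Multi-syllable archetypes (Phee-n has n
#' whistles, Twitter eight rapid upsweeps, Chirp three short notes) place
#' silent gaps between syllables. The parameters sketch the call types'
#' spectrogram shapes; they claim no bioacoustic fidelity - their job is to
#' give the pipeline eleven acoustically distinct, LPC-separable classes.
#'
#' @param names Optional subset of archetype names to return.
#' @return A tibble with one row per archetype: `name`, `profile`
#'   (`tonal` / `broadband` / `mixed`), `carrier_hz`, `bw_hz` (noise-band
#'   half width), `fm_rate_hz`, `fm_depth_hz`, `sweep_hz` (linear up-sweep
#'   across each syllable), `n_syllables`, `syllable_s`, `gap_s`.
#' @export
call_archetypes <- function(names = NULL) {
  a <- tibble::tribble(
    ~name,         ~profile,    ~carrier_hz, ~bw_hz, ~fm_rate_hz, ~fm_depth_hz, ~sweep_hz, ~n_syllables, ~syllable_s, ~gap_s,
    "Alarm",       "broadband", 5500,        1000,   0,           0,            0,         1L,           0.12,        0,
    "Chirp",       "tonal",     4400,        0,      0,           0,            1200,      3L,           0.05,        0.05,
    "Loud-shrill", "tonal",     8800,        0,      8,           100,          0,         1L,           0.60,        0,
    "Phee-2",      "tonal",     7200,        0,      0,           0,            250,       2L,           0.35,        0.15,
    "Phee-3",      "tonal",     7200,        0,      0,           0,            250,       3L,           0.35,        0.15,
    "Phee-4",      "tonal",     7200,        0,      0,           0,            250,       4L,           0.35,        0.15,
    "Seep",        "tonal",     9500,        0,      0,           0,            -300,      1L,           0.10,        0,
    "Trill",       "tonal",     6000,        0,      30,          500,          0,         1L,           0.40,        0,
    "Tsik",        "broadband", 8200,        1200,   0,           0,            0,         1L,           0.08,        0,
    "Tsik-ek",     "mixed",     8200,        1200,   0,           0,            0,         2L,           0.08,        0.06,
    "Twitter",     "tonal",     6500,        0,      0,           0,            2400,      8L,           0.04,        0.04
  )
  if (!is.null(names)) {
    missing <- setdiff(names, a$name)
    if (length(missing) > 0L) {
      stop("unknown archetype(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    a <- a[match(names, a$name), , drop = FALSE]
  }
  a
}

#' Names of the eight principal-class archetypes
#'
#' The well-separated subset used for eight-class experiments: one
#' representative per principal call type (Phee represented by Phee-2,
#' Tsik by Tsik).
#'
#' @return Character vector of eight archetype names.
#' @export
principal_archetypes <- function() {
  c("Alarm", "Chirp", "Loud-shrill", "Phee-2", "Seep", "Trill", "Tsik",
    "Twitter")
}

# one syllable waveform at the given rate
.synth_syllable <- function(profile, carrier, bw, fm_rate, fm_depth, sweep,
                            dur, rate) {
  n <- max(8L, round(dur * rate))
  t <- (0:(n - 1)) / rate
  env <- sin(pi * pmin(1, pmax(0, t / dur)))^2   # smooth on/offset
  if (profile == "broadband") {
    noise <- stats::rnorm(n + 200L)
    bf <- signal::butter(4, c(carrier - bw, carrier + bw) / (rate / 2),
                         type = "pass")
    y <- signal::filter(bf, noise)[-(1:200)]     # drop filter transient
    y <- y / max(stats::sd(y), 1e-12)
  } else {
    f_inst <- carrier + sweep * (t / dur - 0.5) +
      fm_depth * sin(2 * pi * fm_rate * t)
    phase <- 2 * pi * cumsum(f_inst) / rate
    y <- sin(phase)
  }
  y * env
}

#' Synthesize one call
#'
#' Deterministic given `(archetype, seed)`: the call's syllables are laid
#' out with their gaps, 0.6 s of context is added on both sides, and white
#' noise at `noise_level` times the call RMS is mixed over the whole clip.
#' Peak amplitude is normalized to 0.8.
#'
#' @param archetype An archetype name or a one-row tibble from
#'   [call_archetypes()].
#' @param seed Integer seed.
#' @param noise_level Noise RMS relative to call RMS, in `[0, 1)`.
#' @param rate Sample rate; default 44100 Hz.
#' @param margin_s Silence context on each side; default 0.6 s.
#' @return A [call_recording()] labeled with the archetype name.
#' @export
synth_call <- function(archetype, seed = 1L, noise_level = 0.05,
                       rate = 44100, margin_s = 0.6) {
  if (is.character(archetype)) archetype <- call_archetypes(archetype)
  stopifnot(is.data.frame(archetype), nrow(archetype) == 1L)
  if (!(noise_level >= 0 && noise_level < 1)) {
    stop("`noise_level` must be in [0, 1)", call. = FALSE)
  }
  a <- as.list(archetype)
  set.seed(seed)
  gap <- numeric(round(a$gap_s * rate))
  syllables <- lapply(seq_len(a$n_syllables), function(i) {
    if (a$profile == "mixed" && i > 1L) {
      .synth_syllable("tonal", a$carrier_hz * 0.6, 0, 0, 0, 0,
                      a$syllable_s * 1.4, rate)
    } else {
      prof <- if (a$profile == "mixed") "broadband" else a$profile
      .synth_syllable(prof, a$carrier_hz, a$bw_hz, a$fm_rate_hz,
                      a$fm_depth_hz, a$sweep_hz, a$syllable_s, rate)
    }
  })
  body <- syllables[[1L]]
  for (s in syllables[-1L]) body <- c(body, gap, s)
  margin <- numeric(round(margin_s * rate))
  y <- c(margin, body, margin)
  if (noise_level > 0) {
    y <- y + stats::rnorm(length(y), sd = noise_level * stats::sd(body))
  }
  y <- 0.8 * y / max(abs(y))
  call_recording(y, rate = rate, label = a$name,
                 source_id = sprintf("synth:%s:%d", a$name, seed))
}

#' Synthesize a labeled dataset of calls
#'
#' Generates `n_per_class` exemplars per archetype with seeded per-call
#' jitter (+/-10% syllable duration, +/-5% carrier frequency), mirroring a
#' corpus of a few dozen hand-labeled exemplars per call type. Optionally
#' writes 16-bit WAV files plus a `manifest.csv` (columns `file`, `label`)
#' compatible with [load_dataset()].
#'
#' @param n_per_class Exemplars per archetype (>= 2).
#' @param classes Archetype names or a [call_archetypes()]-shaped tibble;
#'   default all 11.
#' @param seed Base seed; every call's waveform is a pure function of
#'   `(seed, class, exemplar index)`.
#' @param noise_level Relative noise RMS; default 0.05.
#' @param out_dir Directory to write WAVs + manifest into; `NULL` (default)
#'   keeps everything in memory.
#' @return A tibble with `call_id`, `label` and a `recording` list-column
#'   (plus `file` when `out_dir` is given).
#' @export
synth_dataset <- function(n_per_class = 30L, classes = call_archetypes(),
                          seed = 1L, noise_level = 0.05, out_dir = NULL) {
  if (is.character(classes)) classes <- call_archetypes(classes)
  stopifnot(n_per_class >= 2L)
  rows <- list()
  for (ci in seq_len(nrow(classes))) {
    base <- classes[ci, , drop = FALSE]
    for (j in seq_len(n_per_class)) {
      call_seed <- (seed * 131071L + ci * 509L + j) %% .Machine$integer.max
      set.seed(call_seed)
      jit <- base
      jit$syllable_s <- base$syllable_s * stats::runif(1, 0.9, 1.1)
      jit$carrier_hz <- base$carrier_hz * stats::runif(1, 0.95, 1.05)
      rec <- synth_call(jit, seed = call_seed + 1L,
                        noise_level = noise_level)
      rec$label <- base$name
      rows[[length(rows) + 1L]] <- tibble::tibble(
        call_id = sprintf("%s_%03d", base$name, j),
        label = base$name, recording = list(rec))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- paste0(out$call_id, ".wav")
    purrr::walk2(out$recording, files,
                 ~ write_wav(.x, file.path(out_dir, .y)))
    utils::write.csv(data.frame(file = files, label = out$label),
                     file.path(out_dir, "manifest.csv"), row.names = FALSE)
    out$file <- files
  }
  out
}

#' Featurize raw recordings through the full signal pipeline
#'
#' Band-pass filters each recording to the analysis band, threshold-segments
#' it, extracts the (first) segment's waveform and computes its LPC feature
#' vector - i.e. the complete path a raw field recording takes before
#' classification.
#'
#' @param calls Tibble with `label` and `recording` columns.
#' @param order LPC order; default 20.
#' @param low_hz,high_hz Analysis band; defaults 4000/10000 Hz.
#' @param threshold Segmentation threshold (`NULL` = automatic).
#' @param pad_s Segmentation padding; default 0.5 s.
#' @return A feature tibble (`label`, `c1..c<order>`), one row per call.
#' @export
pipeline_featurize <- function(calls, order = 20, low_hz = 4000,
                               high_hz = 10000, threshold = NULL,
                               pad_s = 0.5) {
  segmented <- purrr::map(calls$recording, function(rec) {
    filt <- bandpass_filter(rec, low_hz, high_hz)
    seg <- segment_signal(filt, threshold = threshold, pad_s = pad_s)
    if (nrow(seg) == 0L) {
      stop("no segment found in ", rec$source_id, call. = FALSE)
    }
    extract_segments(filt, seg[1L, ])[[1L]]
  })
  featurize_calls(tibble::tibble(label = calls$label,
                                 recording = segmented), order = order)
}
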