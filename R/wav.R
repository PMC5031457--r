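#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader supporting the formats this corpus uses:
#' PCM 8/16/24/32-bit integer and IEEE float32/float64, any number of
#' channels. Multichannel audio is averaged to mono with a warning, since
#' every downstream stage operates on a single amplitude sequence.
#'
#' @param path Path to a `.wav` file.
#' @param label Optional call-type label to attach to the recording.
#' @return A [call_recording()] with samples scaled to approximately
#'   \[-1, 1\].
#' @export
read_wav <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop("cannot read WAV file: '", path, "' does not exist", call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("'", path, "' is not a RIFF/WAVE file", call. = FALSE)
  }
  readBin(con, "integer", 1, size = 4, endian = "little")  # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("'", path, "' is not a RIFF/WAVE file", call. = FALSE)
  }

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw_fmt[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk", call. = FALSE)
      samples <- .decode_wav_data(con, size, fmt, path)
      # chunks are word-aligned
      if (size %% 2L == 1L) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk in '", path, "'", call. = FALSE)

  if (fmt$n_channels > 1L) {
    warning("'", basename(path), "' has ", fmt$n_channels,
            " channels; averaging to mono")
    samples <- rowMeans(matrix(samples, ncol = fmt$n_channels, byrow = TRUE))
  }
  call_recording(samples, rate = fmt$sample_rate, label = label,
                 source_id = path)
}

.decode_wav_data <- function(con, size, fmt, path) {
  bytes_per <- fmt$bits %/% 8L
  n <- size %/% bytes_per
  if (fmt$audio_format == 3L) {          # IEEE float
    readBin(con, "double", n, size = bytes_per, endian = "little")
  } else if (fmt$audio_format == 1L) {   # integer PCM
    if (fmt$bits == 8L) {
      (readBin(con, "integer", n, size = 1, signed = FALSE) - 128) / 128
    } else if (fmt$bits == 16L) {
      readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      raw <- readBin(con, "raw", size)
      b <- matrix(as.integer(raw), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    } else if (fmt$bits == 32L) {
      readBin(con, "integer", n, size = 4, endian = "little") / 2147483648
    } else {
      stop("unsupported PCM bit depth in '", path, "': ", fmt$bits, call. = FALSE)
    }
  } else {
    stop("unsupported WAV audio format code in '", path, "': ",
         fmt$audio_format, call. = FALSE)
  }
}

#' Write a mono WAV file (16-bit PCM)
#'
#' @param recording A [call_recording()] or a numeric vector of samples.
#' @param path Output path.
#' @param rate Sample rate in Hz; taken from the recording when omitted.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, rate = NULL) {
  if (is_call_recording(recording)) {
    samples <- recording$samples
    rate <- rate %||% recording$rate
  } else {
    samples <- as.numeric(recording)
    if (is.null(rate)) stop("`rate` is required when writing a bare sample vector", call. = FALSE)
  }
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32767))))
  n_bytes <- 2L * length(pcm)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
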