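fs <- 44100

test_that("band-pass filter passes the call band and rejects out-of-band energy", {
  t <- (0:(fs - 1)) / fs
  in_band <- call_recording(sin(2 * pi * 7000 * t))
  out <- bandpass_filter(in_band)
  expect_equal(length(out$samples), length(in_band$samples))
  expect_lt(abs(rms(out$samples) / rms(in_band$samples) - 1), 0.05)

  low <- call_recording(sin(2 * pi * 100 * t))
  expect_lt(rms(bandpass_filter(low)$samples) / rms(low$samples), 0.01)

  dc <- call_recording(rep(1, fs))
  core <- bandpass_filter(dc)$samples[2000:(fs - 2000)]
  expect_lt(max(abs(core)), 1e-10)
})

test_that("band edges outside Nyquist are rejected", {
  rec <- call_recording(rnorm(1000), rate = 8000)
  expect_error(bandpass_filter(rec, 4000, 10000), "Nyquist")
  expect_error(bandpass_filter(rec, -1, 1000), "invalid band")
  expect_error(bandpass_filter(rec, 2000, 1000), "invalid band")
})

test_that("threshold segmentation follows the pad-and-merge rule", {
  # silence: no segments
  expect_equal(nrow(segment_signal(numeric(5 * fs), fs, threshold = 0.1)), 0L)
  expect_equal(nrow(segment_signal(numeric(0), fs, threshold = 0.1)), 0L)

  # single burst 2.0-2.2 s, pad 0.5 -> [1.5, 2.7]
  sig <- numeric(5 * fs)
  sig[(2.0 * fs):(2.2 * fs)] <- 0.5
  seg <- segment_signal(sig, fs, threshold = 0.1, pad_s = 0.5)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start_s, 1.5, tolerance = 1e-3)
  expect_equal(seg$end_s, 2.7, tolerance = 1e-3)

  # two bursts closer than 2 * pad merge into [0.5, 2.1]
  sig2 <- numeric(5 * fs)
  sig2[(1.0 * fs):(1.1 * fs)] <- 0.5
  sig2[(1.5 * fs):(1.6 * fs)] <- 0.5
  seg2 <- segment_signal(sig2, fs, threshold = 0.1, pad_s = 0.5)
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$start_s, 0.5, tolerance = 1e-3)
  expect_equal(seg2$end_s, 2.1, tolerance = 1e-3)

  # far-apart bursts stay separate and are ordered by start time
  sig3 <- numeric(6 * fs)
  sig3[(1.0 * fs):(1.05 * fs)] <- 0.5
  sig3[(4.0 * fs):(4.05 * fs)] <- 0.5
  seg3 <- segment_signal(sig3, fs, threshold = 0.1, pad_s = 0.5)
  expect_equal(nrow(seg3), 2L)
  expect_true(all(diff(seg3$start_s) > 0))

  # spans are clipped to the signal bounds
  sig4 <- numeric(fs)
  sig4[1:100] <- 0.5
  seg4 <- segment_signal(sig4, fs, threshold = 0.1, pad_s = 0.5)
  expect_gte(seg4$start_s, 0)
  expect_lte(seg4$end_s, (fs - 1) / fs)
})

test_that("segmentation is idempotent on an already-isolated padded call", {
  rec <- synth_call("Trill", seed = 11, noise_level = 0.02)
  filt <- bandpass_filter(rec)
  seg <- segment_signal(filt)
  expect_equal(nrow(seg), 1L)
  clip <- extract_segments(filt, seg)[[1]]
  seg2 <- segment_signal(clip)
  expect_equal(nrow(seg2), 1L)
})

test_that("filtering then segmenting recovers a call buried in low-frequency noise", {
  set.seed(5)
  t <- (0:(5 * fs - 1)) / fs
  hum <- 0.4 * sin(2 * pi * 60 * t) + 0.2 * sin(2 * pi * 300 * t)
  call <- ifelse(t >= 2 & t <= 2.4, 0.5 * sin(2 * pi * 7000 * t), 0)
  rec <- call_recording(hum + call)
  filt <- bandpass_filter(rec)
  seg <- segment_signal(filt, threshold = 0.1, pad_s = 0.5)
  expect_equal(nrow(seg), 1L)
  expect_lt(abs(seg$start_s - 1.5), 0.5)
  expect_lt(abs(seg$end_s - 2.9), 0.5)
})

test_that("WAV files round-trip through write_wav / read_wav", {
  dir <- withr::local_tempdir()
  rec <- synth_call("Chirp", seed = 2, noise_level = 0.05)
  path <- file.path(dir, "chirp.wav")
  write_wav(rec, path)
  back <- read_wav(path, label = "Chirp")
  expect_equal(back$rate, rec$rate)
  expect_equal(length(back$samples), length(rec$samples))
  expect_equal(back$samples, rec$samples, tolerance = 1e-3)  # 16-bit quantization
  expect_equal(back$label, "Chirp")
})

test_that("load_dataset honours the manifest contract", {
  dir <- withr::local_tempdir()
  ds <- synth_dataset(2, c("Trill", "Seep", "Tsik"), seed = 4,
                      out_dir = dir)
  loaded <- load_dataset(file.path(dir, "manifest.csv"))
  expect_equal(nrow(loaded), 6L)
  expect_setequal(unique(loaded$label), c("Trill", "Seep", "Tsik"))
  expect_true(all(loaded$rate == 44100))

  # empty manifest -> empty result
  empty <- file.path(dir, "empty.csv")
  writeLines("file,label", empty)
  expect_equal(nrow(load_dataset(empty)), 0L)

  # missing file -> I/O error naming the file
  bad <- file.path(dir, "bad.csv")
  writeLines(c("file,label", "nope.wav,Trill"), bad)
  expect_error(load_dataset(bad), "nope.wav")

  # unknown label against a fixed class list
  expect_error(
    load_dataset(file.path(dir, "manifest.csv"), classes = c("Trill", "Seep")),
    "unknown label"
  )
})

test_that("call_recording validates its invariants", {
  expect_error(call_recording(numeric(0)), "non-empty")
  expect_error(call_recording(c(1, NA)), "finite")
  expect_error(call_recording(1:10, rate = 0), "positive")
})
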