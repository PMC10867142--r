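test_that("WAV write/read round trip stays within 16-bit quantization", {
  fs <- 44100
  x <- 0.7 * sin(2 * pi * 200 * seq(0, 1, by = 1 / fs))
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav_file(x, fs, path)
  rec <- read_call(path, call_id = "t")
  expect_s3_class(rec, "call_recording")
  expect_equal(rec$sample_rate_hz, fs)
  expect_equal(length(rec$samples), length(x))
  expect_lt(max(abs(rec$samples - x)), 2^-15)
})

test_that("stereo input with identical channels mixes to that channel", {
  fs <- 8000
  x <- 0.5 * sin(2 * pi * 100 * seq(0, 0.5, by = 1 / fs))
  path <- withr::local_tempfile(fileext = ".wav")
  # hand-build a 2-channel PCM file
  q <- as.integer(round(x * 32767))
  inter <- as.vector(rbind(q, q))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + length(inter) * 2), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(inter) * 2), con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  rec <- read_call(path)
  expect_lt(max(abs(rec$samples - q / 32768)), 1e-12)
})

test_that("malformed audio input is rejected", {
  bad <- withr::local_tempfile(fileext = ".wav")
  writeLines("not audio at all, just text padding to get past size", bad)
  expect_error(read_call(bad), "RIFF")
  expect_error(call_recording(numeric(0), 44100), "non-empty")
  expect_error(call_recording(c(0.1, NaN), 44100), "NaN")
})

test_that("manifest loads rows, folds case, and reports unreadable files", {
  dir <- withr::local_tempdir()
  fs <- 44100
  for (i in 1:3) {
    write_wav_file(0.5 * sin(2 * pi * 150 * seq(0, 0.3, by = 1 / fs)), fs,
                   file.path(dir, sprintf("c%d.wav", i)))
  }
  manifest <- file.path(dir, "manifest.csv")
  write.csv(data.frame(call_id = c("a", "b", "c"),
                       wav_path = c("c1.wav", "c2.wav", "c3.wav"),
                       cow_id = "cow1", call_type = c("hf", "LF", "Lf")),
            manifest, row.names = FALSE)
  recs <- load_manifest(manifest)
  expect_length(recs, 3)
  expect_equal(vapply(recs, `[[`, "", "call_id"), c("a", "b", "c"))
  expect_equal(vapply(recs, `[[`, "", "call_type"), c("HF", "LF", "LF"))

  write.csv(data.frame(call_id = c("a", "b", "gone"),
                       wav_path = c("c1.wav", "c2.wav", "missing.wav"),
                       cow_id = "cow1", call_type = "HF"),
            manifest, row.names = FALSE)
  expect_warning(recs2 <- load_manifest(manifest), "skipping")
  expect_length(recs2, 2)
  expect_equal(nrow(attr(recs2, "skipped")), 1)

  write.csv(data.frame(call_id = "a", wav_path = "c1.wav"), manifest,
            row.names = FALSE)
  expect_error(load_manifest(manifest), "missing required column")
})

test_that("spectrogram grid shape is fixed and a tone is localized", {
  st <- spectrogram_settings()
  for (dur in c(0.5, 1, 2.3)) {
    s <- compute_spectrogram(tone_recording(1000, dur = dur), st)
    expect_equal(dim(s$power_db), c(1000, 250))
  }
  s <- compute_spectrogram(tone_recording(1000), st)
  avg <- colMeans(s$power_linear)
  fhat <- s$freq_axis[which.max(avg)]
  bin <- diff(s$freq_axis[1:2])
  expect_lt(abs(fhat - 1000), bin + 1e-9)
  # >= 90% of spectral power within +/- 3 bins of the tone
  sel <- abs(s$freq_axis - fhat) <= 3 * bin
  expect_gte(sum(avg[sel]) / sum(avg), 0.9)
  # dynamic range clipping
  set.seed(1)
  sil <- call_recording(rnorm(44100) * 1e-9 + 1e-8, 44100, "sil")
  sq <- compute_spectrogram(sil, st)
  expect_lte(max(sq$power_db) - min(sq$power_db), st$dynamic_range_db + 1e-9)
  expect_error(compute_spectrogram(tone_recording(500, dur = 0.01), st),
               "shorter")
})

test_that("envelope measures stationary level, steps, and silence", {
  fs <- 44100
  # 200 Hz: an integer number of periods per 30 ms frame, so the RMS is exact
  env <- compute_envelope(tone_recording(200, dur = 1))
  interior <- env$level_db[env$times > 0.1 & env$times < 0.9]
  expect_lt(max(interior) - min(interior), 0.1)

  x <- sin(2 * pi * 220 * seq(0, 2, by = 1 / fs)) * 0.3
  x[seq_along(x) > length(x) / 2] <- x[seq_along(x) > length(x) / 2] * 2
  env2 <- compute_envelope(call_recording(x, fs, "step"))
  lo <- median(env2$level_db[env2$times > 0.2 & env2$times < 0.8])
  hi <- median(env2$level_db[env2$times > 1.2 & env2$times < 1.8])
  expect_equal(hi - lo, 20 * log10(2), tolerance = 0.2 / 6)

  env3 <- compute_envelope(call_recording(rep(0, fs), fs, "zero"))
  expect_true(all(env3$level_db == -120))
})

test_that("synthesized calls keep their silence padding 40 dB down", {
  corpus <- tiny_corpus()
  rec <- corpus$recordings[[1]]
  gt <- corpus$ground_truth[1, ]
  env <- compute_envelope(rec)
  pad <- env$times < gt$t_on_s - 0.05 | env$times > gt$t_off_s + 0.05
  expect_true(all(env$level_db[pad] <= max(env$level_db) - 40))
})
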