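test_that("F0 tracking: pure tone, noise rejection, ramp following", {
  co <- estimate_f0_contour(tone_recording(300))
  expect_gte(mean(co$voiced), 0.9)
  expect_true(all(abs(co$f0_hz[co$voiced] - 300) <= 2))

  set.seed(42)
  noise <- call_recording(rnorm(44100) * 0.3, 44100, "wn")
  expect_lte(mean(estimate_f0_contour(noise)$voiced), 0.1)

  # linear F0 ramp with known schedule (synthesizer-style chirp)
  fs <- 44100
  t <- seq(0, 1.5, by = 1 / fs)
  f0_t <- 100 + (200 - 100) * t / max(t)
  ph <- 2 * pi * cumsum(f0_t) / fs
  x <- 0
  for (h in 1:10) x <- x + (1 / h) * cos(h * ph)
  ramp <- call_recording(0.8 * x / max(abs(x)), fs, "ramp")
  co <- estimate_f0_contour(ramp)
  sched <- 100 + 100 * co$times / max(t)
  err <- abs(co$f0_hz[co$voiced] - sched[co$voiced])
  expect_gte(mean(co$voiced), 0.8)
  expect_true(all(err <= 5))
})

test_that("F0 statistics are plain arithmetic over voiced frames", {
  co <- structure(list(times = 1:3 / 100, f0_hz = c(100, 150, 200),
                       voiced = rep(TRUE, 3)), class = "f0_contour")
  expect_equal(unname(f0_statistics(co)), c(150, 200, 100, 100))
  co$f0_hz <- rep(300, 3)
  expect_equal(unname(f0_statistics(co)), c(300, 300, 300, 0))
  co$voiced <- rep(FALSE, 3)
  expect_error(f0_statistics(co), "no voiced")
})

test_that("spectral quartiles follow the cumulative-energy convention", {
  s <- spectral_distribution_features(tone_recording(1000))
  binw <- 44100 / 2048  # STFT bin width at the 0.03 s analysis window
  expect_true(all(abs(s[c("Q25", "Q50", "Q75", "Fpeak")] - 1000) < 3 * binw))

  fs <- 44100
  t <- seq(0, 1, by = 1 / fs)
  # the lower tone carries slightly over half the energy, so under the ">="
  # convention Q25 and Q50 both sit at the lower tone (exact equality of the
  # two windowed peaks is knife-edge numerically)
  two <- call_recording(0.44 * sin(2 * pi * 500 * t) + 0.40 * sin(2 * pi * 1500 * t),
                        fs, "two")
  s2 <- spectral_distribution_features(two)
  expect_lt(abs(s2[["Q25"]] - 500), 3 * binw)
  expect_lt(abs(s2[["Q50"]] - 500), 3 * binw)
  expect_lt(abs(s2[["Q75"]] - 1500), 3 * binw)

  # band-limited white noise 0-4000 Hz: Q50 near 2000
  set.seed(3)
  nz <- rnorm(fs)
  nf <- stats::fft(nz)
  f <- seq(0, fs - 1)  # 1 s of audio: bin k sits at k Hz
  keep <- pmin(f, fs - f) <= 4000
  bl <- Re(stats::fft(nf * keep, inverse = TRUE)) / fs
  s3 <- spectral_distribution_features(call_recording(bl / max(abs(bl)), fs, "bl"))
  expect_equal(unname(s3[["Q50"]]), 2000, tolerance = 0.1)

  expect_error(spectral_distribution_features(
    call_recording(rep(1e-300, 1000), 1000, "z")), "degenerate|shorter")
})

test_that("duration gating matches the synthesizer's gate times", {
  corpus <- tiny_corpus()
  errs <- abs(vapply(seq_along(corpus$recordings), function(i) {
    env <- compute_envelope(corpus$recordings[[i]])
    measure_duration(env) - corpus$ground_truth$duration_s[i]
  }, 0))
  expect_lt(median(errs), 0.02)

  env_flat <- structure(list(times = seq(0, 1, 0.01),
                             level_db = rep(-20, 101),
                             frame_s = 0.03, hop_s = 0.01),
                        class = "bovine_envelope")
  expect_equal(measure_duration(env_flat), 1)
  expect_equal(measure_duration(env_flat, mode = "file"), 1 + 0.01)

  env_spike <- env_flat
  env_spike$level_db <- c(rep(-80, 50), -10, rep(-80, 50))
  expect_equal(measure_duration(env_spike), 0.01)  # floored at one hop
})

test_that("amplitude-modulation metrics recover a known modulation", {
  env_flat <- structure(list(times = seq(0, 2, 0.01),
                             level_db = rep(-15, 201),
                             frame_s = 0.03, hop_s = 0.01),
                        class = "bovine_envelope")
  am0 <- amplitude_modulation_features(env_flat, 2)
  expect_equal(unname(am0), c(0, 0, 0))

  tt <- seq(0, 2, 0.01)
  lev <- -20 + 3 * sin(2 * pi * 5 * tt)   # 6 dB peak-to-trough at 5 Hz
  env <- structure(list(times = tt, level_db = lev, frame_s = 0.03,
                        hop_s = 0.01), class = "bovine_envelope")
  am <- amplitude_modulation_features(env, 2)
  expect_equal(unname(am[["AMRate"]]), 5, tolerance = 0.5 / 5)
  expect_equal(unname(am[["AMExtent"]]), 6, tolerance = 1 / 6)
  expect_equal(unname(am[["AMVar"]]), sum(abs(diff(lev))) / 2, tolerance = 0.05)

  expect_error(amplitude_modulation_features(env, 0), "positive")
})

test_that("harmonicity reflects the signal-to-noise construction", {
  expect_gte(harmonicity(tone_recording(300)), 30)
  fs <- 44100
  t <- seq(0, 1, by = 1 / fs)
  s <- sin(2 * pi * 300 * t)
  # periodicity is measured in the pitch-analysis band, so the known-SNR
  # construction band-limits the noise to that band (~0-5.5 kHz)
  n_samp <- length(t)
  set.seed(7)
  raw <- rnorm(n_samp)
  keep <- pmin(seq(0, n_samp - 1), n_samp - seq(0, n_samp - 1)) *
    fs / n_samp <= 5500
  bl <- Re(stats::fft(stats::fft(raw) * keep, inverse = TRUE)) / n_samp
  hnrs <- vapply(c(0, 10, 20), function(snr) {
    n <- bl * sqrt(mean(s^2) / 10^(snr / 10)) / sqrt(mean(bl^2))
    harmonicity(call_recording(0.8 * (s + n) / max(abs(s + n)), fs, "sn"))
  }, 0)
  expect_equal(hnrs[2], 10, tolerance = 2 / 10)
  expect_true(hnrs[3] > hnrs[2])
  expect_true(hnrs[2] > hnrs[1])
})

test_that("formants of a uniform-tube call are recovered with its spacing", {
  p <- make_cow_profile("tube", 1)
  p$formant_spacing_hz <- c(mean = 1200, sd = 0)
  out <- synthesize_call(p, "LF", seed = 2)
  ff <- formant_features(out$recording)
  truth <- (2 * seq_len(8) - 1) * 600
  expect_true(all(abs(ff[1:8] - truth) / truth <= 0.10))
  expect_equal(unname(ff[["formant_dispersal"]]), 1200, tolerance = 0.1)
  # dispersal is the minimum consecutive gap of the reported means
  expect_equal(unname(ff[["formant_dispersal"]]), min(diff(ff[1:8])))
})

test_that("wiener entropy is zero for flat spectra and penalizes tonality", {
  flat <- matrix(3.7, nrow = 10, ncol = 50)
  expect_equal(wiener_entropy_mean(flat), 0)
  set.seed(5)
  anyp <- matrix(rexp(500), nrow = 10)
  expect_lte(wiener_entropy_mean(anyp), 0)
  set.seed(6)
  noise <- call_recording(rnorm(44100) * 0.3, 44100, "n")
  s_noise <- native_frames_for_test(noise)
  s_tone <- native_frames_for_test(tone_recording(300))
  expect_gt(wiener_entropy_mean(s_noise), wiener_entropy_mean(s_tone))
  expect_error(wiener_entropy_mean(matrix(numeric(0), 0, 0)), "empty")
})

test_that("extract_features returns the canonical schema deterministically", {
  rec <- tiny_corpus()$recordings[[2]]
  f1 <- extract_features(rec)
  f2 <- extract_features(rec)
  expect_identical(f1, f2)
  expect_equal(names(f1), c("call_id", "cow_id", "call_type", vocal_feature_names))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(f1, path)
  expect_equal(readLines(path, n = 1), paste0(
    "\"call_id\",\"cow_id\",\"call_type\",\"",
    paste(vocal_feature_names, collapse = "\",\""), "\""))
  # gain invariance: all 23 parameters are level-relative
  louder <- call_recording(rec$samples * 0.5, rec$sample_rate_hz,
                           rec$call_id, rec$cow_id, rec$call_type)
  f3 <- extract_features(louder)
  for (nm in vocal_feature_names) {
    expect_equal(f3[[nm]], f1[[nm]], tolerance = 0.02, label = nm)
  }
})
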