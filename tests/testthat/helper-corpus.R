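# Shared fixtures, generated once per test run and memoised.
# The demo corpus is the package's reference study condition: 5 cows x 40
# calls, seed 7, HF fraction 0.832.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

demo_corpus <- function() {
  memo("demo_corpus", synthesize_corpus(5, 40, hf_fraction = 0.832, seed = 7))
}

demo_features <- function() {
  memo("demo_features", extract_feature_table(demo_corpus()$recordings))
}

demo_spectrograms <- function() {
  memo("demo_spectrograms",
       prepare_spectrogram_batch(demo_corpus()$recordings, grid = c(64, 32)))
}

tiny_corpus <- function() {
  # closer-to-balanced mix so even 3-fold stratification works on 18 calls
  memo("tiny_corpus", synthesize_corpus(3, 6, hf_fraction = 0.6, seed = 11))
}

# fast ensemble settings used throughout the tests (desk-scale search)
fast_ctrl <- function() ensemble_control("fast")

# separable numeric table: first column carries the signal, the rest noise
separable_table <- function(n = 120, m = 6, gap = 4, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  y <- rep(c("LF", "HF"), length.out = n)
  x[, 1] <- x[, 1] + ifelse(y == "HF", gap / 2, -gap / 2)
  colnames(x) <- paste0("f", seq_len(m))
  df <- data.frame(call_id = as.character(seq_len(n)), cow_id = "c",
                   call_type = y, x, stringsAsFactors = FALSE)
  feature_table(df, "call_type", feature_cols = colnames(x))
}

# linear-power STFT frames of a recording (for spectral-flatness checks)
native_frames_for_test <- function(rec) {
  bovinecall:::native_power_frames(rec)$power
}

# pure tone as a call_recording
tone_recording <- function(freq, dur = 1, fs = 44100, amp = 0.8) {
  call_recording(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / fs)), fs,
                 call_id = paste0("tone", freq))
}
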