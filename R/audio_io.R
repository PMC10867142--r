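#' Construct a call recording object
#'
#' A `call_recording` holds one pre-segmented vocalization: the mono waveform
#' (amplitude-normalized to `[-1, 1]`), its sampling rate, and identity /
#' label metadata.
#'
#' @param samples Numeric vector of finite samples in `[-1, 1]`.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param call_id Identifier string for the call.
#' @param cow_id Identifier of the calling animal, or `""` if unknown.
#' @param call_type One of `"LF"`, `"HF"`, `"UNKNOWN"` (case-insensitive).
#' @return An object of class `call_recording`.
#' @export
call_recording <- function(samples, sample_rate_hz, call_id = "call",
                           cow_id = "", call_type = "UNKNOWN") {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("call_recording: samples must be non-empty")
  if (any(!is.finite(samples))) stop("call_recording: samples contain NaN/Inf")
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("call_recording: sample_rate_hz must be a positive integer")
  }
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      call_id = as.character(call_id),
      cow_id = as.character(cow_id),
      call_type = parse_call_type(call_type)
    ),
    class = "call_recording"
  )
}

parse_call_type <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (length(x) != 1 || is.na(x) || x == "") return("UNKNOWN")
  if (!x %in% c("LF", "HF", "UNKNOWN")) return("UNKNOWN")
  x
}

#' @export
print.call_recording <- function(x, ...) {
  cat(sprintf("call_recording '%s': %.3f s @ %d Hz, cow='%s', type=%s\n",
              x$call_id, length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, x$cow_id, x$call_type))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A `call_recording`.
#' @return Length of the waveform divided by the sampling rate.
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$sample_rate_hz

#' Read one call from a WAV file
#'
#' Reads an uncompressed PCM WAV file; multi-channel input is mixed to mono by
#' channel averaging. If `target_rate_hz` is given and differs from the file's
#' rate, the waveform is resampled (with a warning).
#'
#' @param path Path to the WAV file.
#' @param call_id Call identifier (defaults to the file name).
#' @param cow_id,call_type Optional label metadata.
#' @param target_rate_hz Optional rate to resample to (e.g. 44100).
#' @return A [call_recording()].
#' @export
read_call <- function(path, call_id = NULL, cow_id = "", call_type = "UNKNOWN",
                      target_rate_hz = NULL) {
  w <- read_wav_file(path)
  x <- rowMeans(w$samples)
  rate <- w$sample_rate_hz
  if (!is.null(target_rate_hz) && rate != target_rate_hz) {
    warning(sprintf("resampling %s from %d to %d Hz", path, rate,
                    as.integer(target_rate_hz)))
    x <- signal::resample(x, p = target_rate_hz, q = rate)
    rate <- as.integer(target_rate_hz)
  }
  call_recording(x, rate,
                 call_id = call_id %||% tools::file_path_sans_ext(basename(path)),
                 cow_id = cow_id, call_type = call_type)
}

#' Load a manifest CSV of call recordings
#'
#' The manifest has header columns `call_id,wav_path,cow_id,call_type`;
#' relative `wav_path`s are resolved against the manifest's directory. Rows
#' whose WAV cannot be read are skipped with a warning and collected into the
#' `skipped` attribute of the result.
#'
#' @param path Path to the manifest CSV.
#' @return A list of [call_recording()]s, with attribute `skipped` (a
#'   data.frame of unreadable rows and the error messages).
#' @export
load_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("call_id", "wav_path", "cow_id", "call_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  recs <- list()
  skipped <- data.frame(call_id = character(), wav_path = character(),
                        error = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    wav <- df$wav_path[i]
    if (!file.exists(wav)) wav <- file.path(base, df$wav_path[i])
    rec <- tryCatch(
      read_call(wav, call_id = df$call_id[i], cow_id = df$cow_id[i],
                call_type = df$call_type[i]),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      warning(sprintf("skipping row %d (%s): %s", i, df$call_id[i],
                      conditionMessage(rec)))
      skipped <- rbind(skipped, data.frame(
        call_id = df$call_id[i], wav_path = df$wav_path[i],
        error = conditionMessage(rec), stringsAsFactors = FALSE))
    } else {
      recs[[length(recs) + 1L]] <- rec
    }
  }
  attr(recs, "skipped") <- skipped
  recs
}

#' Spectrogram analysis settings
#'
#' Defaults follow the standard narrow-band viewing convention for cattle
#' calls: 0.03 s Gaussian analysis windows, a 1000 x 250 (time x frequency)
#' output grid, 60 dB dynamic range and a 0-5000 Hz view ceiling.
#'
#' @param window_s Analysis window length in seconds.
#' @param n_time_steps,n_freq_steps Output grid resolution.
#' @param dynamic_range_db Values below `max - dynamic_range_db` are clipped.
#' @param view_fmax_hz Upper frequency bound of the grid, Hz.
#' @return A list of class `spectrogram_settings`.
#' @export
spectrogram_settings <- function(window_s = 0.03, n_time_steps = 1000,
                                 n_freq_steps = 250, dynamic_range_db = 60,
                                 view_fmax_hz = 5000) {
  stopifnot(window_s > 0, n_time_steps > 0, n_freq_steps > 0,
            dynamic_range_db > 0, view_fmax_hz > 0)
  structure(list(window_s = window_s, n_time_steps = as.integer(n_time_steps),
                 n_freq_steps = as.integer(n_freq_steps),
                 dynamic_range_db = dynamic_range_db,
                 view_fmax_hz = view_fmax_hz),
            class = "spectrogram_settings")
}

# Short-time power spectra with a Gaussian window at given frame centers.
# Returns linear power, rows = frames, cols = FFT bins up to Nyquist.
stft_power <- function(x, fs, window_s, centers_s) {
  wlen <- max(8L, round(window_s * fs))
  if (wlen %% 2 == 1) wlen <- wlen + 1L
  nfft <- 2^ceiling(log2(wlen))
  # Gaussian window, effective length = window_s (edges near -60 dB)
  tt <- seq(-(wlen - 1) / 2, (wlen - 1) / 2)
  win <- exp(-0.5 * (tt / (wlen / 6))^2)
  half <- wlen %/% 2
  n <- length(x)
  nbins <- nfft %/% 2 + 1L
  pow <- matrix(0, nrow = length(centers_s), ncol = nbins)
  xpad <- c(rep(0, half), x, rep(0, half + 1))
  for (i in seq_along(centers_s)) {
    c0 <- round(centers_s[i] * fs) + 1L  # sample index of frame center
    idx <- (c0):(c0 + wlen - 1L)         # within xpad: centered on c0
    frame <- xpad[idx] * win
    sp <- stats::fft(c(frame, rep(0, nfft - wlen)))
    pow[i, ] <- Mod(sp[seq_len(nbins)])^2 / sum(win^2)
  }
  list(power = pow, freq = seq(0, fs / 2, length.out = nbins),
       times = centers_s, nfft = nfft)
}

#' Compute a spectrogram on a fixed analysis grid
#'
#' Short-time power spectra over Gaussian windows of `settings$window_s`,
#' resampled onto the `n_time_steps` x `n_freq_steps` output grid spanning the
#' call's duration and 0 to `view_fmax_hz`. Power is expressed in dB and
#' clipped to `dynamic_range_db` below the maximum; the pre-clipping linear
#' power is retained for spectral-flatness measures.
#'
#' @param rec A [call_recording()].
#' @param settings A [spectrogram_settings()].
#' @return Object of class `bovine_spectrogram` with elements `power_db`
#'   (clipped, time x frequency), `power_linear` (unclipped), `time_axis`,
#'   `freq_axis`, `settings`.
#' @export
compute_spectrogram <- function(rec, settings = spectrogram_settings()) {
  stopifnot(inherits(rec, "call_recording"))
  dur <- rec_duration(rec)
  if (dur < settings$window_s) {
    stop(sprintf("recording (%.3f s) shorter than one analysis window (%.3f s)",
                 dur, settings$window_s))
  }
  fs <- rec$sample_rate_hz
  # native frames every 5 ms (or finer for very short calls), then linear
  # interpolation onto the requested grid
  hop <- min(0.005, dur / 50)
  native_t <- seq(0, dur, by = hop)
  s <- stft_power(rec$samples, fs, settings$window_s, native_t)
  t_grid <- seq(0, dur, length.out = settings$n_time_steps)
  f_grid <- seq(0, settings$view_fmax_hz, length.out = settings$n_freq_steps)
  # interpolate in frequency first (usually the bigger reduction), then time
  pf <- t(apply(s$power, 1, function(row) {
    stats::approx(s$freq, row, xout = f_grid, rule = 2)$y
  }))
  pt <- apply(pf, 2, function(col) {
    stats::approx(native_t, col, xout = t_grid, rule = 2)$y
  })
  power_linear <- matrix(pt, nrow = settings$n_time_steps)
  eps <- .Machine$double.xmin
  db <- 10 * log10(pmax(power_linear, eps))
  db <- pmax(db, max(db) - settings$dynamic_range_db)
  structure(list(power_db = db, power_linear = power_linear,
                 time_axis = t_grid, freq_axis = f_grid, settings = settings),
            class = "bovine_spectrogram")
}

#' @export
print.bovine_spectrogram <- function(x, ...) {
  cat(sprintf("spectrogram: %d time steps x %d frequency steps, 0-%g Hz, %g dB range\n",
              nrow(x$power_db), ncol(x$power_db), max(x$freq_axis),
              x$settings$dynamic_range_db))
  invisible(x)
}

#' Frame-wise amplitude envelope in dB
#'
#' Per-frame RMS level in dB relative to full scale (sample value 1.0), with
#' frames of `frame_s` centered every `hop_s`. Silent frames are floored at
#' -120 dB.
#'
#' @param rec A [call_recording()].
#' @param frame_s Frame length in seconds.
#' @param hop_s Hop between frame centers in seconds.
#' @return Object of class `bovine_envelope`: `times` (s), `level_db`,
#'   `frame_s`, `hop_s`.
#' @export
compute_envelope <- function(rec, frame_s = 0.03, hop_s = 0.01) {
  stopifnot(inherits(rec, "call_recording"))
  dur <- rec_duration(rec)
  if (dur < frame_s) stop("recording shorter than one envelope frame")
  fs <- rec$sample_rate_hz
  wlen <- max(2L, round(frame_s * fs))
  half <- wlen %/% 2
  centers <- seq(0, dur, by = hop_s)
  xpad <- c(rep(0, half), rec$samples, rep(0, half + 1))
  csum <- cumsum(c(0, xpad^2))
  i0 <- pmax(1L, round(centers * fs) + 1L)
  rms <- sqrt((csum[i0 + wlen] - csum[i0]) / wlen)
  structure(list(times = centers, level_db = amp_to_db(rms),
                 frame_s = frame_s, hop_s = hop_s),
            class = "bovine_envelope")
}
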