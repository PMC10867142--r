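#' Draw a per-cow synthetic voice profile
#'
#' Encodes cow individuality the way field studies attribute it: in the base
#' fundamental frequency (per call type), the formant spacing of the vocal
#' tract (a uniform-tube proxy, so shorter tracts give wider spacing), the
#' amplitude-modulation rate, and call duration. Low-frequency (LF,
#' closed-mouth) and high-frequency (HF, open-mouth) calls differ primarily in
#' their F0 band.
#'
#' @param cow_id Identifier string.
#' @param seed Integer seed; the same `(cow_id, seed)` pair always yields the
#'   same profile.
#' @param f0_lf_range,f0_hf_range Hyper-ranges (Hz) the per-cow base F0 means
#'   are drawn from.
#' @param spacing_range Hyper-range (Hz) for the formant spacing mean.
#' @param duration_range Hyper-range (s) for mean call duration.
#' @return A list of class `cow_profile`.
#' @export
make_cow_profile <- function(cow_id, seed,
                             f0_lf_range = c(70, 120),
                             f0_hf_range = c(250, 600),
                             spacing_range = c(500, 1300),
                             duration_range = c(0.5, 2.5)) {
  with_seed(derive_seed(seed, "profile", cow_id), {
    f0_lf <- stats::runif(1, f0_lf_range[1], f0_lf_range[2])
    f0_hf <- stats::runif(1, f0_hf_range[1], f0_hf_range[2])
    dur_lf <- stats::runif(1, duration_range[1], duration_range[1] +
                             0.6 * diff(duration_range))
    dur_hf <- stats::runif(1, duration_range[1] + 0.2 * diff(duration_range),
                           duration_range[2])
    structure(list(
      cow_id = as.character(cow_id),
      f0_lf_hz = c(mean = f0_lf, sd = 0.04 * f0_lf),
      f0_hf_hz = c(mean = f0_hf, sd = 0.04 * f0_hf),
      f0_drift = stats::runif(1, 0.05, 0.25),
      formant_spacing_hz = c(mean = stats::runif(1, spacing_range[1], spacing_range[2]),
                             sd = 0.02 * mean(spacing_range)),
      am_rate_hz = c(mean = stats::runif(1, 2, 8), sd = 0.4),
      am_extent_db = stats::runif(1, 3, 8),
      duration_s = list(LF = c(mean = dur_lf, sd = 0.08 * dur_lf),
                        HF = c(mean = dur_hf, sd = 0.08 * dur_hf)),
      hnr_db = stats::runif(1, 18, 28),
      seed = as.integer(seed)
    ), class = "cow_profile")
  })
}

#' @export
print.cow_profile <- function(x, ...) {
  cat(sprintf("cow_profile '%s': F0 LF %.0f Hz / HF %.0f Hz, spacing %.0f Hz, AM %.1f Hz\n",
              x$cow_id, x$f0_lf_hz["mean"], x$f0_hf_hz["mean"],
              x$formant_spacing_hz["mean"], x$am_rate_hz["mean"]))
  invisible(x)
}

#' Synthesize one cattle-like call with known ground truth
#'
#' Source-filter synthesis: a harmonic glottal source following a linear F0
#' ramp is shaped by a vocal-tract magnitude envelope with eight Lorentzian
#' resonances placed at odd multiples of half the drawn formant spacing
#' (uniform-tube layout, -6 dB/octave tilt). Aspiration noise shaped by the
#' same envelope is mixed in at the drawn SNR, and the call is
#' amplitude-gated with raised-cosine onset/offset and sinusoidally
#' amplitude-modulated. Every parameter actually drawn is returned as the
#' ground-truth record.
#'
#' @param profile A [make_cow_profile()] result.
#' @param call_type `"LF"` or `"HF"`.
#' @param seed Integer seed; synthesis is bit-reproducible given
#'   `(profile, call_type, seed)`.
#' @param call_id Optional identifier; defaults to a composed one.
#' @param sample_rate_hz Output rate (44100 canonical).
#' @param pad_s Leading/trailing digital silence around the gated call.
#' @return List with `recording` (a [call_recording()]) and `ground_truth`
#'   (one-row data.frame).
#' @export
synthesize_call <- function(profile, call_type = c("HF", "LF"), seed,
                            call_id = NULL, sample_rate_hz = 44100,
                            pad_s = 0.25) {
  call_type <- match.arg(call_type)
  fs <- sample_rate_hz
  call_id <- call_id %||% sprintf("%s_%s_s%d", profile$cow_id, call_type, seed)
  with_seed(derive_seed(seed, "call", profile$cow_id, call_type), {
    f0p <- if (call_type == "LF") profile$f0_lf_hz else profile$f0_hf_hz
    f0_base <- max(40, stats::rnorm(1, f0p["mean"], f0p["sd"]))
    drift <- stats::runif(1, -profile$f0_drift, profile$f0_drift)
    durp <- profile$duration_s[[call_type]]
    duration <- min(3, max(0.3, stats::rnorm(1, durp["mean"], durp["sd"])))
    spacing <- max(300, stats::rnorm(1, profile$formant_spacing_hz["mean"],
                                     profile$formant_spacing_hz["sd"]))
    formants <- (2 * seq_len(8) - 1) * spacing / 2
    am_rate <- max(0.5, stats::rnorm(1, profile$am_rate_hz["mean"],
                                     profile$am_rate_hz["sd"]))
    am_extent <- profile$am_extent_db
    snr_db <- max(15, stats::rnorm(1, profile$hnr_db, 2))

    n_total <- round((duration + 2 * pad_s) * fs)
    t <- (seq_len(n_total) - 1) / fs
    t_on <- pad_s
    t_off <- pad_s + duration

    # F0 schedule: linear ramp f0_base*(1 - drift/2) -> f0_base*(1 + drift/2)
    # across the gated span, constant outside (irrelevant there: gated to 0)
    frac <- pmin(pmax((t - t_on) / duration, 0), 1)
    f0_t <- f0_base * (1 - drift / 2 + drift * frac)
    f0_start <- f0_base * (1 - drift / 2)
    f0_end <- f0_base * (1 + drift / 2)

    # Vocal-tract magnitude envelope: one Lorentzian resonance per formant
    # with a -6 dB/octave source tilt. Additive harmonic synthesis under this
    # envelope keeps every resonance peak exactly at its nominal frequency
    # (no cascade tilt or parallel-bank interference), so the drawn formant
    # centers are exact ground truth for the analysis side.
    bws <- 60 + 0.03 * formants
    envfun <- function(f) {
      E <- 0
      for (k in seq_len(8)) {
        E <- E + (formants[1] / formants[k]) /
          (1 + ((f - formants[k]) / (bws[k] / 2))^2)
      }
      E
    }

    # harmonic stack following the F0 ramp; per-harmonic amplitude tracks the
    # envelope at the harmonic's instantaneous frequency (coarse grid +
    # interpolation: the ramp is slow)
    ph0 <- 2 * pi * cumsum(f0_t) / fs
    f_syn_max <- 10500
    n_harm <- max(1L, floor(f_syn_max / max(f0_start, f0_end)))
    # per-harmonic amplitude follows the envelope at the harmonic's
    # instantaneous frequency; evaluated on a coarse grid (the ramp is slow)
    # and linearly interpolated with precomputed segment indices
    n_coarse <- 200L
    gpos <- 1 + (seq_len(n_total) - 1) * (n_coarse - 1) / (n_total - 1)
    seg <- pmin(floor(gpos), n_coarse - 1L)
    fracs <- gpos - seg
    f0_coarse <- f0_t[round(seq(1L, n_total, length.out = n_coarse))]
    # coherent (zero) harmonic phases: a pulse-like glottal waveform, as in a
    # real larynx; keeps the waveform periodicity unambiguous. cos(h*ph0) is
    # built by the Chebyshev recurrence to avoid n_harm transcendental passes.
    sig <- numeric(n_total)
    c1 <- cos(ph0)
    c_prev <- rep(1, n_total)
    c_cur <- c1
    for (h in seq_len(n_harm)) {
      va <- envfun(h * f0_coarse)
      if (max(va) > 1e-4) {
        amp <- va[seg] + fracs * (va[seg + 1L] - va[seg])
        sig <- sig + amp * c_cur
      }
      c_next <- 2 * c1 * c_cur - c_prev
      c_prev <- c_cur
      c_cur <- c_next
    }

    # aspiration noise shaped by the same envelope (FFT filtering on a
    # power-of-two length), mixed at the drawn SNR: the periodic-to-aperiodic
    # power ratio sets harmonicity
    nfft <- 2^ceiling(log2(n_total))
    nz <- stats::rnorm(nfft)
    kbin <- 0:(nfft - 1)
    fbin <- pmin(kbin, nfft - kbin) * fs / nfft
    nzs <- Re(stats::fft(stats::fft(nz) * envfun(fbin), inverse = TRUE)) / nfft
    nzs <- nzs[seq_len(n_total)]
    nzs <- nzs * sqrt(mean(sig^2) / 10^(snr_db / 10)) / sqrt(mean(nzs^2))
    sig <- sig + nzs
    sig <- sig / max(abs(sig))

    # sinusoidal AM with dB peak-to-trough depth am_extent
    m <- (10^(am_extent / 20) - 1) / (10^(am_extent / 20) + 1)
    am <- 1 + m * sin(2 * pi * am_rate * (t - t_on))

    # raised-cosine gate, 20 ms edges, inside [t_on, t_off]
    ramp <- 0.02
    gate <- ifelse(t < t_on | t > t_off, 0,
                   ifelse(t < t_on + ramp, 0.5 * (1 - cos(pi * (t - t_on) / ramp)),
                          ifelse(t > t_off - ramp,
                                 0.5 * (1 - cos(pi * (t_off - t) / ramp)), 1)))

    x <- sig * am * gate
    x <- 0.9 * x / max(abs(x))

    gt <- data.frame(
      call_id = call_id, cow_id = profile$cow_id, call_type = call_type,
      f0_mean_hz = f0_base, f0_start_hz = f0_start, f0_end_hz = f0_end,
      f0_min_hz = min(f0_start, f0_end), f0_max_hz = max(f0_start, f0_end),
      duration_s = duration, t_on_s = t_on, t_off_s = t_off,
      formant_spacing_hz = spacing,
      F1_hz = formants[1], F2_hz = formants[2], F3_hz = formants[3],
      F4_hz = formants[4], F5_hz = formants[5], F6_hz = formants[6],
      F7_hz = formants[7], F8_hz = formants[8],
      am_rate_hz = am_rate, am_extent_db = am_extent, snr_db = snr_db,
      stringsAsFactors = FALSE
    )
    list(recording = call_recording(x, fs, call_id = call_id,
                                    cow_id = profile$cow_id,
                                    call_type = call_type),
         ground_truth = gt)
  })
}

#' Generate an in-memory labelled corpus of synthetic calls
#'
#' Draws `n_cows` voice profiles and `calls_per_cow` calls per cow, each call
#' HF with probability `hf_fraction` (default mirrors the 952/1144 HF share
#' typical of isolation recordings).
#'
#' @param n_cows,calls_per_cow Corpus dimensions.
#' @param hf_fraction Expected HF share per call.
#' @param seed Master seed; the whole corpus is reproducible from it.
#' @return List with `recordings` (list of [call_recording()]) and
#'   `ground_truth` (data.frame, one row per call).
#' @export
synthesize_corpus <- function(n_cows, calls_per_cow, hf_fraction = 0.832,
                              seed = 1) {
  stopifnot(n_cows >= 1, calls_per_cow >= 1, hf_fraction >= 0, hf_fraction <= 1)
  recs <- vector("list", n_cows * calls_per_cow)
  gts <- vector("list", n_cows * calls_per_cow)
  idx <- 0L
  for (c_i in seq_len(n_cows)) {
    cow <- sprintf("cow%02d", c_i)
    profile <- make_cow_profile(cow, seed)
    types <- with_seed(derive_seed(seed, "types", cow), {
      ifelse(stats::runif(calls_per_cow) < hf_fraction, "HF", "LF")
    })
    for (j in seq_len(calls_per_cow)) {
      idx <- idx + 1L
      out <- synthesize_call(profile, types[j],
                             seed = derive_seed(seed, "draw", cow, j),
                             call_id = sprintf("%s_c%03d", cow, j))
      recs[[idx]] <- out$recording
      gts[[idx]] <- out$ground_truth
    }
  }
  list(recordings = recs, ground_truth = do.call(rbind, gts))
}

#' Generate a synthetic corpus on disk (WAV files + manifest + ground truth)
#'
#' Writes one 16-bit 44.1 kHz WAV per call, a manifest CSV
#' (`call_id,wav_path,cow_id,call_type`) and `ground_truth.csv` into
#' `out_dir`.
#'
#' @inheritParams synthesize_corpus
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly; attributes `ground_truth_path`
#'   and `n_calls`.
#' @export
generate_corpus <- function(n_cows, calls_per_cow, hf_fraction = 0.832,
                            out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  corpus <- synthesize_corpus(n_cows, calls_per_cow, hf_fraction, seed)
  rows <- lapply(corpus$recordings, function(rec) {
    wav <- paste0(rec$call_id, ".wav")
    write_wav_file(rec$samples, rec$sample_rate_hz, file.path(out_dir, wav))
    data.frame(call_id = rec$call_id, wav_path = wav, cow_id = rec$cow_id,
               call_type = rec$call_type, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  gt_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(corpus$ground_truth, gt_path, row.names = FALSE)
  structure(invisible(manifest_path), ground_truth_path = gt_path,
            n_calls = nrow(manifest))
}
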