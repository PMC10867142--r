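#' Names of the 23 vocal parameters, in canonical order
#'
#' Fundamental-frequency statistics, spectral energy quartiles and peak,
#' duration, amplitude-modulation metrics, harmonicity, eight formant means,
#' formant dispersal and mean Wiener entropy.
#' @export
vocal_feature_names <- c(
  "F0Mean", "F0Max", "F0Min", "F0Range",
  "Q25", "Q50", "Q75", "Fpeak",
  "sound_duration", "AMVar", "AMRate", "AMExtent", "harmonicity",
  "F1Mean", "F2Mean", "F3Mean", "F4Mean",
  "F5Mean", "F6Mean", "F7Mean", "F8Mean",
  "formant_dispersal", "wiener_entropy_mean"
)

#' Feature-extraction configuration
#'
#' All thresholds of the extraction pipeline in one place.
#'
#' @param f0_floor_hz,f0_ceiling_hz Pitch search range (cattle calls can reach
#'   F0 above 1000 Hz, hence the wide ceiling).
#' @param voicing_threshold Minimum normalized autocorrelation for a frame to
#'   count as voiced.
#' @param gate_db Duration gate: the call spans the frames within `gate_db`
#'   of the envelope peak.
#' @param duration_mode `"gate"` (oscillogram-style gating) or `"file"` (whole
#'   file length, for pre-trimmed corpora).
#' @param n_formants,formant_ceiling_hz,formant_bw_max_hz Formant analysis:
#'   number of formants retained, analysis ceiling (signal is resampled to
#'   twice this), and maximum accepted candidate bandwidth.
#' @param lpc_order Linear-prediction order for formant analysis; two poles
#'   per expected resonance.
#' @param am_prominence_db Minimum peak prominence for an envelope maximum to
#'   count as an amplitude modulation.
#' @param envelope_frame_s,envelope_hop_s Envelope framing.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(f0_floor_hz = 30, f0_ceiling_hz = 1500,
                           voicing_threshold = 0.45,
                           gate_db = 25, duration_mode = c("gate", "file"),
                           n_formants = 8, formant_ceiling_hz = 10000,
                           formant_bw_max_hz = 600, lpc_order = 20,
                           am_prominence_db = 2,
                           envelope_frame_s = 0.03, envelope_hop_s = 0.01) {
  duration_mode <- match.arg(duration_mode)
  structure(as.list(environment()), class = "feature_config")
}

# ---------------------------------------------------------------------------
# Pitch / periodicity machinery (shared by F0 contour and harmonicity)

# Frame-wise normalized autocorrelation analysis at a decimated rate.
# Returns per-frame times, best normalized ACF peak r, f0 estimate, frame
# level (dB re max frame), and the voiced flags.
pitch_analysis <- function(rec, f_floor, f_ceiling, voicing_threshold = 0.45) {
  fs <- rec$sample_rate_hz
  x <- rec$samples
  q <- max(1L, floor(fs / 11025))
  if (q > 1) {
    x <- signal::decimate(x, q)
    fs <- fs / q
  }
  if (f_ceiling >= fs / 2) f_ceiling <- fs / 2 - 1
  wlen <- round(max(0.03, 2 / f_floor) * fs)
  dur <- length(x) / fs
  hop <- 0.01
  if (length(x) < wlen + 2) {
    return(list(times = numeric(0), f0_hz = numeric(0), voiced = logical(0),
                r = numeric(0)))
  }
  starts <- seq(1L, length(x) - wlen, by = max(1L, round(hop * fs)))
  centers <- (starts - 1 + wlen / 2) / fs
  lmin <- max(2L, floor(fs / f_ceiling))
  lmax <- min(wlen - 2L, ceiling(fs / f_floor))
  nfft <- 2^ceiling(log2(wlen + lmax + 1))
  # The ACF of a broadband harmonic stack has peaks only ~1 sample wide at
  # this rate, so the ACF is evaluated on a 4x-finer lag grid by band-limited
  # (sinc) interpolation: zero-padding the power spectrum before the inverse
  # transform. `up` is the lag oversampling factor.
  up <- 4L
  fine_acf <- function(p_spec) {
    half <- nfft %/% 2
    pf <- c(p_spec[1:half], p_spec[half + 1] / 2,
            rep(0, (up - 1L) * nfft - 1L),
            p_spec[half + 1] / 2, p_spec[(half + 2):nfft])
    Re(stats::fft(pf, inverse = TRUE))
  }
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))
  wac <- fine_acf(Mod(stats::fft(c(win, rep(0, nfft - wlen))))^2)
  wac <- wac / wac[1]
  lag_fine <- seq_len(up * lmax) / up        # lags in samples, step 1/up
  keep <- lag_fine >= lmin & lag_fine <= lmax
  wseg <- pmax(wac[2:(up * lmax + 1)][keep], 1e-6)

  n_frames <- length(starts)
  r_best <- numeric(n_frames)
  f0 <- rep(NA_real_, n_frames)
  power <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    seg <- x[starts[i]:(starts[i] + wlen - 1L)]
    seg <- seg - mean(seg)
    power[i] <- mean(seg^2)
    if (power[i] <= 0) next
    xf <- c(seg * win, rep(0, nfft - wlen))
    ac <- fine_acf(Mod(stats::fft(xf))^2)
    if (ac[1] <= 0) next
    rn <- pmin((ac[2:(up * lmax + 1)][keep] / ac[1]) / wseg, 1)
    # Candidate lags are the local ACF maxima in the search range. A periodic
    # signal peaks equally at every multiple of its period, so the shortest
    # candidate within a small tolerance of the best peak is taken: this
    # suppresses subharmonic (octave-down) errors without letting a dominant
    # formant (much weaker peak at short lag) capture the track.
    locmax <- which(diff(sign(diff(rn))) < 0) + 1L
    cands <- unique(c(locmax, which.max(rn)))
    best <- max(rn[cands])
    # 0.035 sits between the noise fluctuation of equal-height subharmonic
    # peaks (~0.01-0.02) and the deficit of a dominant-partial "whistle"
    # peak (~0.05+), so both failure modes lose to the true period
    k <- min(cands[rn[cands] >= best - 0.035])
    # parabolic refinement on the fine grid
    if (k > 1 && k < length(rn)) {
      y0 <- rn[k - 1]; y1 <- rn[k]; y2 <- rn[k + 1]
      denom <- y0 - 2 * y1 + y2
      delta <- if (abs(denom) > 1e-12) 0.5 * (y0 - y2) / denom else 0
      delta <- max(-1, min(1, delta))
      peak <- y1 - 0.25 * (y0 - y2) * delta
      lag <- lag_fine[keep][k] + delta / up
    } else {
      peak <- rn[k]; lag <- lag_fine[keep][k]
    }
    r_best[i] <- min(peak, 1 - 1e-9)
    f0[i] <- fs / lag
  }
  level <- 10 * log10(pmax(power, .Machine$double.xmin))
  level <- level - max(level)
  # frames well below the loudest frame are onset/offset ringing, not voice
  voiced <- r_best >= voicing_threshold & level >= -25 & !is.na(f0)
  # median filter (width 5) over the voiced track to remove octave blips
  vi <- which(voiced)
  if (length(vi) >= 5) {
    f0v <- f0[vi]
    f0s <- f0v
    n_v <- length(f0v)
    for (j in seq_len(n_v)) {
      f0s[j] <- stats::median(f0v[max(1, j - 2):min(n_v, j + 2)])
    }
    f0[vi] <- f0s
    # contour-consistency guard: frames more than 0.8 octave from the call's
    # median voiced F0 are onset/offset transients or residual octave errors
    med <- stats::median(f0[vi])
    voiced[vi][abs(log2(f0[vi] / med)) > 0.8] <- FALSE
  }
  f0[!voiced] <- NA_real_
  list(times = centers, f0_hz = f0, voiced = voiced,
       r = pmin(pmax(r_best, 0), 1 - 1e-6))
}

#' Estimate the fundamental-frequency contour
#'
#' Frame-wise autocorrelation pitch tracking (normalized ACF with parabolic
#' peak interpolation and a width-3 median filter), with frames below the
#' voicing threshold, or more than 35 dB below the loudest frame, marked
#' unvoiced.
#'
#' @param rec A [call_recording()].
#' @param f_floor,f_ceiling Pitch search range in Hz.
#' @param voicing_threshold Normalized-ACF threshold for voicing.
#' @return Object of class `f0_contour`: `times`, `f0_hz` (NA when unvoiced),
#'   `voiced`.
#' @export
estimate_f0_contour <- function(rec, f_floor = 30, f_ceiling = 1500,
                                voicing_threshold = 0.45) {
  stopifnot(inherits(rec, "call_recording"), f_floor > 0, f_floor < f_ceiling)
  pa <- pitch_analysis(rec, f_floor, f_ceiling, voicing_threshold)
  structure(list(times = pa$times, f0_hz = pa$f0_hz, voiced = pa$voiced),
            class = "f0_contour")
}

#' Summary statistics of an F0 contour
#'
#' Mean, maximum, minimum over voiced frames, and the range computed exactly
#' as maximum minus minimum.
#'
#' @param contour An [estimate_f0_contour()] result.
#' @return Named vector `c(F0Mean, F0Max, F0Min, F0Range)` in Hz.
#' @export
f0_statistics <- function(contour) {
  v <- contour$f0_hz[contour$voiced]
  if (length(v) == 0) stop("f0_statistics: no voiced frame in the call")
  c(F0Mean = mean(v), F0Max = max(v), F0Min = min(v),
    F0Range = max(v) - min(v))
}

#' Harmonic-to-noise ratio (harmonicity) in dB
#'
#' Per voiced frame, `HNR = 10 log10(r / (1 - r))` with `r` the maximum
#' normalized autocorrelation in the pitch lag range; the mean over voiced
#' frames is returned. Higher values indicate a more tonal call.
#'
#' @inheritParams estimate_f0_contour
#' @return Mean HNR in dB.
#' @export
harmonicity <- function(rec, f_floor = 30, f_ceiling = 1500,
                        voicing_threshold = 0.45) {
  pa <- pitch_analysis(rec, f_floor, f_ceiling, voicing_threshold)
  if (!any(pa$voiced)) stop("harmonicity: call has no voiced frame")
  r <- pmin(pmax(pa$r[pa$voiced], 1e-6), 1 - 1e-6)
  mean(10 * log10(r / (1 - r)))
}

# ---------------------------------------------------------------------------
# Spectral distribution

# Resample by a rational ratio, reduced to lowest terms first.
resample_ratio <- function(x, p, q) {
  g <- gcd_int(round(p), round(q))
  signal::resample(x, p = round(p) / g, q = round(q) / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Native-resolution STFT over the whole recording: 0.03 s windows, 10 ms hop.
native_power_frames <- function(rec, window_s = 0.03, hop_s = 0.01) {
  dur <- rec_duration(rec)
  centers <- seq(window_s / 2, max(window_s / 2, dur - window_s / 2),
                 by = hop_s)
  stft_power(rec$samples, rec$sample_rate_hz, window_s, centers)
}

#' Energy quartiles and peak frequency of the time-averaged spectrum
#'
#' Computed on the time-averaged power spectrum of the call: `Qx` is the
#' lowest frequency at which the cumulative energy fraction reaches `x`;
#' `Fpeak` is the frequency of maximum power.
#'
#' @param rec A [call_recording()].
#' @return Named vector `c(Q25, Q50, Q75, Fpeak)` in Hz.
#' @export
spectral_distribution_features <- function(rec) {
  s <- native_power_frames(rec)
  spec <- colMeans(s$power)
  tot <- sum(spec)
  if (!is.finite(tot) || tot <= 0) {
    stop("spectral_distribution_features: degenerate all-zero spectrum")
  }
  cum <- cumsum(spec) / tot
  qat <- function(p) s$freq[which(cum >= p)[1]]
  c(Q25 = qat(0.25), Q50 = qat(0.50), Q75 = qat(0.75),
    Fpeak = s$freq[which.max(spec)])
}

# ---------------------------------------------------------------------------
# Duration and amplitude modulation

# Gated span of the call: first/last envelope frame within gate_db of peak.
call_span <- function(env, gate_db = 25) {
  thr <- max(env$level_db) - gate_db
  idx <- which(env$level_db >= thr)
  c(env$times[idx[1]], env$times[idx[length(idx)]])
}

#' Call duration from the amplitude envelope
#'
#' Time between the first and last envelope frame whose level is within
#' `gate_db` of the peak (the oscillogram-style measure). A degenerate
#' single-frame span is floored at one hop. With `mode = "file"` the full
#' recording length is returned (for pre-trimmed corpora).
#'
#' @param env A [compute_envelope()] result.
#' @param gate_db Gate depth below the envelope peak, dB.
#' @param mode `"gate"` or `"file"`.
#' @return Duration in seconds.
#' @export
measure_duration <- function(env, gate_db = 25, mode = c("gate", "file")) {
  mode <- match.arg(mode)
  if (mode == "file") {
    return(env$times[length(env$times)] - env$times[1] + env$hop_s)
  }
  span <- call_span(env, gate_db)
  max(span[2] - span[1], env$hop_s)
}

# Prominence of each local maximum of a series (walk out both sides until a
# higher sample or the boundary; prominence = peak - max of the two side
# minima).
peak_prominences <- function(v) {
  n <- length(v)
  is_peak <- which(diff(sign(diff(v))) < 0) + 1L
  prom <- numeric(length(is_peak))
  for (j in seq_along(is_peak)) {
    p <- is_peak[j]
    lmin <- v[p]; i <- p
    while (i > 1 && v[i] <= v[p]) { i <- i - 1; lmin <- min(lmin, v[i]) }
    if (v[i] <= v[p]) lmin <- min(v[1:p])
    rmin <- v[p]; i <- p
    while (i < n && v[i] <= v[p]) { i <- i + 1; rmin <- min(rmin, v[i]) }
    if (v[i] <= v[p]) rmin <- min(v[p:n])
    prom[j] <- v[p] - max(lmin, rmin)
  }
  list(peaks = is_peak, prominence = prom)
}

#' Amplitude-modulation metrics of the call envelope
#'
#' `AMVar` is the cumulative variation of the dB envelope divided by the call
#' duration (dB/s). `AMRate` is the number of envelope maxima with prominence
#' at least `prominence_db`, per second. `AMExtent` is the mean modulation
#' depth: for each pair of consecutive detected peaks, the mean peak level
#' minus the intervening trough, averaged over cycles.
#'
#' @param env Envelope restricted to the measured call span.
#' @param duration Call duration in seconds (> 0).
#' @param prominence_db Minimum peak prominence in dB.
#' @return Named vector `c(AMVar, AMRate, AMExtent)`.
#' @export
amplitude_modulation_features <- function(env, duration, prominence_db = 2) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("amplitude_modulation_features: duration must be positive")
  }
  v <- env$level_db
  am_var <- sum(abs(diff(v))) / duration
  pp <- peak_prominences(v)
  keep <- pp$peaks[pp$prominence >= prominence_db]
  am_rate <- length(keep) / duration
  if (length(keep) >= 2) {
    depths <- numeric(length(keep) - 1)
    for (j in seq_len(length(keep) - 1)) {
      trough <- min(v[keep[j]:keep[j + 1]])
      depths[j] <- (v[keep[j]] + v[keep[j + 1]]) / 2 - trough
    }
    am_extent <- mean(depths)
  } else {
    am_extent <- 0
  }
  c(AMVar = am_var, AMRate = am_rate, AMExtent = am_extent)
}

# ---------------------------------------------------------------------------
# Formants

#' Formant frequency means and formant dispersal
#'
#' Pre-emphasized, resampled to twice the analysis ceiling, then frame-wise
#' linear prediction (Burg) of order `2 * n_formants + 4` (two spare pole
#' pairs absorb the glottal line and residual spectral tilt); polynomial roots
#' with bandwidth below `bw_max_hz` become formant candidates, sorted
#' ascending, the first `n_formants` retained per frame. `FkMean` averages the
#' k-th candidate over frames offering at least k candidates. Formant
#' dispersal is the minimum spacing between consecutive defined formant
#' means.
#'
#' @param rec A [call_recording()].
#' @param n_formants Number of formants (8 for cattle-call work).
#' @param ceiling_hz Analysis ceiling in Hz.
#' @param bw_max_hz Maximum accepted candidate bandwidth in Hz.
#' @param lpc_order Linear-prediction order (default two poles per formant).
#' @return Named vector `F1Mean ... FnMean` (NA for never-filled slots) plus
#'   `formant_dispersal`.
#' @export
formant_features <- function(rec, n_formants = 8, ceiling_hz = 10000,
                             bw_max_hz = 600, lpc_order = 2 * n_formants + 4) {
  fs0 <- rec$sample_rate_hz
  target <- 2 * ceiling_hz
  if (fs0 < target) stop("sample rate too low for the requested formant ceiling")
  x <- if (fs0 != target) {
    resample_ratio(rec$samples, target, fs0)
  } else rec$samples
  fs <- target
  # Adaptive effective ceiling: when the call's (pre-emphasized) energy sits
  # well below the nominal ceiling, the analysis band is narrowed so the
  # prediction poles are spent on the occupied band - the usual per-recording
  # ceiling adjustment of formant practice, automated.
  alpha0 <- exp(-2 * pi * 50 / fs)
  xp <- c(x[1], x[-1] - alpha0 * x[-length(x)])
  avg <- native_power_frames(call_recording(xp, fs, rec$call_id))
  spec <- colMeans(avg$power)
  f_occ <- avg$freq[which(cumsum(spec) / sum(spec) >= 0.975)[1]]
  eff_ceiling <- min(ceiling_hz, max(3000, 1.15 * f_occ))
  if (eff_ceiling < 0.95 * ceiling_hz) {
    eff_target <- 2 * round(eff_ceiling / 50) * 50
    x <- resample_ratio(x, eff_target, fs)
    fs <- eff_target
    ceiling_hz <- fs / 2
  }
  # pre-emphasis from 50 Hz
  alpha <- exp(-2 * pi * 50 / fs)
  x <- c(x[1], x[-1] - alpha * x[-length(x)])
  order <- lpc_order
  wlen <- round(0.025 * fs)
  hop <- round(0.01 * fs)
  if (length(x) < wlen + 2) stop("recording too short for formant analysis")
  starts <- seq(1L, length(x) - wlen, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, wlen - 1) / (wlen - 1))
  power <- vapply(starts, function(s0) mean(x[s0:(s0 + wlen - 1)]^2), 0)
  lev <- 10 * log10(pmax(power, .Machine$double.xmin))
  use <- which(lev >= max(lev) - 30)
  cand <- matrix(NA_real_, nrow = length(use), ncol = n_formants)
  for (i in seq_along(use)) {
    seg <- x[starts[use[i]]:(starts[use[i]] + wlen - 1L)]
    seg <- (seg - mean(seg)) * win
    a <- tryCatch(stats::ar.burg(seg, aic = FALSE, order.max = order,
                                 demean = FALSE)$ar,
                  error = function(e) NULL)
    if (is.null(a) || length(a) < 1) next
    # roots of 1 - sum(a_i w^i) are reciprocals of the AR poles: modulus > 1
    # for a stable fit, bandwidth = (fs/pi) * ln|w|
    z <- polyroot(c(1, -a))
    f <- Arg(z) * fs / (2 * pi)  # keep the positive-frequency member of each pair
    bw <- log(pmax(Mod(z), 1 + 1e-12)) * fs / pi
    ok <- f > 50 & f < ceiling_hz - 50 & bw < bw_max_hz
    f <- sort(f[ok])
    if (length(f) > 0) cand[i, seq_len(min(length(f), n_formants))] <-
        f[seq_len(min(length(f), n_formants))]
  }
  means <- vapply(seq_len(n_formants), function(k) {
    vals <- cand[, k]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, 0)
  names(means) <- paste0("F", seq_len(n_formants), "Mean")
  defined <- which(!is.na(means))
  runs <- defined[which(diff(defined) == 1)]
  if (length(runs) < 1) {
    stop("formant_features: fewer than two consecutive formant means defined")
  }
  gaps <- means[runs + 1] - means[runs]
  c(means, formant_dispersal = unname(min(gaps)))
}

# ---------------------------------------------------------------------------
# Wiener entropy

#' Mean Wiener entropy (log spectral flatness)
#'
#' Per frame, flatness is the geometric mean over arithmetic mean of the
#' linear power bins; the value returned is the mean over frames of
#' `ln(flatness)`, which is 0 for an exactly flat spectrum and negative
#' (tonal) otherwise.
#'
#' @param spec A `bovine_spectrogram` (its pre-clipping linear power is used)
#'   or a numeric matrix of linear power, frames x bins.
#' @return Mean log flatness (<= 0).
#' @export
wiener_entropy_mean <- function(spec) {
  p <- if (inherits(spec, "bovine_spectrogram")) spec$power_linear else spec
  if (!is.matrix(p) || nrow(p) == 0 || ncol(p) == 0) {
    stop("wiener_entropy_mean: empty spectrogram")
  }
  p <- pmax(p, .Machine$double.eps)
  lnflat <- rowMeans(log(p)) - log(rowMeans(p))
  mean(pmin(lnflat, 0))
}

# ---------------------------------------------------------------------------
# Orchestration

#' Extract the 23 vocal parameters from one call
#'
#' Runs the full measurement pipeline on the gated call span: envelope and
#' duration, F0 contour statistics, spectral energy quartiles and peak,
#' amplitude-modulation metrics, harmonicity, eight formant means with
#' dispersal, and mean Wiener entropy. Features whose sub-measure is
#' undefined (e.g. F0 of an unvoiced call) are returned as NA and the row is
#' flagged.
#'
#' @param rec A [call_recording()].
#' @param config A [feature_config()].
#' @return One-row data.frame: `call_id`, `cow_id`, `call_type`, then the 23
#'   columns of [vocal_feature_names], with attribute `flagged` (TRUE if any
#'   feature is undefined).
#' @export
extract_features <- function(rec, config = feature_config()) {
  stopifnot(inherits(rec, "call_recording"))
  env <- compute_envelope(rec, config$envelope_frame_s, config$envelope_hop_s)
  duration <- measure_duration(env, config$gate_db, config$duration_mode)
  span <- if (config$duration_mode == "file") {
    c(env$times[1], env$times[length(env$times)])
  } else call_span(env, config$gate_db)

  # trim the waveform to the gated span (small margin keeps edge frames whole)
  fs <- rec$sample_rate_hz
  margin <- config$envelope_frame_s / 2
  i0 <- max(1L, floor((span[1] - margin) * fs) + 1L)
  i1 <- min(length(rec$samples), ceiling((span[2] + margin) * fs))
  trimmed <- call_recording(rec$samples[i0:i1], fs, rec$call_id, rec$cow_id,
                            rec$call_type)

  keep <- env$times >= span[1] & env$times <= span[2]
  env_span <- structure(list(times = env$times[keep],
                             level_db = env$level_db[keep],
                             frame_s = env$frame_s, hop_s = env$hop_s),
                        class = "bovine_envelope")
  am <- amplitude_modulation_features(env_span, duration,
                                      config$am_prominence_db)

  out <- stats::setNames(as.list(rep(NA_real_, length(vocal_feature_names))),
                         vocal_feature_names)
  pa <- pitch_analysis(trimmed, config$f0_floor_hz, config$f0_ceiling_hz,
                       config$voicing_threshold)
  if (any(pa$voiced)) {
    v <- pa$f0_hz[pa$voiced]
    out$F0Mean <- mean(v); out$F0Max <- max(v); out$F0Min <- min(v)
    out$F0Range <- out$F0Max - out$F0Min
    r <- pmin(pmax(pa$r[pa$voiced], 1e-6), 1 - 1e-6)
    out$harmonicity <- mean(10 * log10(r / (1 - r)))
  }
  sd <- tryCatch(spectral_distribution_features(trimmed),
                 error = function(e) NULL)
  if (!is.null(sd)) {
    out$Q25 <- sd[["Q25"]]; out$Q50 <- sd[["Q50"]]; out$Q75 <- sd[["Q75"]]
    out$Fpeak <- sd[["Fpeak"]]
  }
  out$sound_duration <- duration
  out$AMVar <- am[["AMVar"]]; out$AMRate <- am[["AMRate"]]
  out$AMExtent <- am[["AMExtent"]]
  ff <- tryCatch(formant_features(trimmed, config$n_formants,
                                  config$formant_ceiling_hz,
                                  config$formant_bw_max_hz,
                                  config$lpc_order),
                 error = function(e) NULL)
  if (!is.null(ff)) {
    for (k in seq_len(config$n_formants)) {
      out[[paste0("F", k, "Mean")]] <- ff[[paste0("F", k, "Mean")]]
    }
    out$formant_dispersal <- ff[["formant_dispersal"]]
  }
  # Wiener entropy on the call-span spectrogram band (0 - view ceiling)
  s <- native_power_frames(trimmed)
  band <- s$freq <= spectrogram_settings()$view_fmax_hz
  out$wiener_entropy_mean <- wiener_entropy_mean(s$power[, band, drop = FALSE])

  row <- data.frame(call_id = rec$call_id, cow_id = rec$cow_id,
                    call_type = rec$call_type, stringsAsFactors = FALSE)
  row <- cbind(row, as.data.frame(out))
  attr(row, "flagged") <- anyNA(row[, vocal_feature_names])
  row
}

#' Extract features for a whole corpus
#'
#' @param recordings List of [call_recording()]s (e.g. from [load_manifest()]
#'   or [synthesize_corpus()]).
#' @param config A [feature_config()].
#' @param drop_flagged Drop rows with any undefined feature (the default;
#'   mirrors keeping only clean calls for model training).
#' @return data.frame with `call_id`, `cow_id`, `call_type` and the 23 feature
#'   columns; attribute `n_flagged` counts excluded rows.
#' @export
extract_feature_table <- function(recordings, config = feature_config(),
                                  drop_flagged = TRUE) {
  rows <- lapply(recordings, extract_features, config = config)
  flagged <- vapply(rows, function(r) isTRUE(attr(r, "flagged")), TRUE)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (drop_flagged && any(flagged)) df <- df[!flagged, , drop = FALSE]
  attr(df, "n_flagged") <- sum(flagged)
  df
}

#' Validate the internal consistency of extracted features
#'
#' Checks the defining relations of the 23 parameters: F0 ordering and exact
#' range, quartile monotonicity, ascending formants with dispersal no larger
#' than the smallest consecutive gap, positive duration, non-negative AM
#' metrics, and non-positive Wiener entropy.
#'
#' @param features A row (or rows) as produced by [extract_features()].
#' @return TRUE invisibly, or an error describing the violated relation.
#' @export
validate_features <- function(features) {
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    id <- f$call_id
    chk <- function(cond, what) {
      if (!isTRUE(cond)) stop(sprintf("feature invariant violated (%s): %s", id, what))
    }
    if (!is.na(f$F0Mean)) {
      chk(f$F0Min <= f$F0Mean && f$F0Mean <= f$F0Max, "F0Min <= F0Mean <= F0Max")
      chk(isTRUE(all.equal(f$F0Range, f$F0Max - f$F0Min)), "F0Range = F0Max - F0Min")
    }
    if (!is.na(f$Q25)) chk(f$Q25 <= f$Q50 && f$Q50 <= f$Q75, "Q25 <= Q50 <= Q75")
    fm <- as.numeric(f[paste0("F", 1:8, "Mean")])
    def <- which(!is.na(fm))
    if (length(def) >= 2) {
      chk(all(diff(fm[def]) > 0), "formant means strictly ascending")
      consec <- def[which(diff(def) == 1)]
      if (length(consec) >= 1 && !is.na(f$formant_dispersal)) {
        gaps <- fm[consec + 1] - fm[consec]
        chk(f$formant_dispersal > 0 &&
              f$formant_dispersal <= min(gaps) + 1e-9,
            "dispersal = min consecutive formant gap")
      }
    }
    chk(f$sound_duration > 0, "positive duration")
    chk(f$AMVar >= 0 && f$AMRate >= 0 && f$AMExtent >= 0, "AM metrics >= 0")
    if (!is.na(f$wiener_entropy_mean)) {
      chk(f$wiener_entropy_mean <= 0, "wiener entropy <= 0")
    }
  }
  invisible(TRUE)
}

#' Write a feature table to CSV with the canonical header
#' @param features data.frame from [extract_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  cols <- c("call_id", "cow_id", "call_type", vocal_feature_names)
  utils::write.csv(features[, cols], path, row.names = FALSE)
  invisible(path)
}
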