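# Envelope-based rhythm estimation, spectral features, and the
# potential-for-identity-coding (PIC) statistic.

#' Amplitude envelope of a vocal sequence
#'
#' Band-pass filters the audio, takes the magnitude of the analytic signal
#' (Hilbert transform), zero-phase low-pass filters it, and (optionally)
#' decimates. Defaults follow the vocal-sequence pipeline: 0.1-10 kHz
#' pre-filter, 20 Hz fourth-order Butterworth envelope smoothing; word
#' streams use 30 Hz / order 8 (see [stream_rates()]).
#'
#' @param audio an [audio_seq].
#' @param band_hz length-2 pre-filter band (Hz); clipped to the Nyquist.
#' @param env_lowpass_hz envelope low-pass cutoff (Hz).
#' @param order Butterworth order of the envelope low-pass.
#' @param decimate_to target envelope rate (Hz), or `NULL` to keep the
#'   audio rate. The default 200 Hz retains everything below the cutoff.
#' @return an object of class `envelope` with fields `values` (>= 0),
#'   `sample_rate`, `lowpass_hz`, `filter_order`.
#' @export
compute_envelope <- function(audio, band_hz = c(100, 10000),
                             env_lowpass_hz = 20, order = 4L,
                             decimate_to = 200) {
  if (!inherits(audio, "audio_seq") || length(audio$samples) == 0)
    abort_canicoh("`audio` must be a non-empty audio_seq",
                  "canicoh_invalid_input")
  sr <- audio$sample_rate
  nyq <- sr / 2
  if (env_lowpass_hz >= nyq)
    abort_canicoh("envelope cutoff must be below the Nyquist frequency",
                  "canicoh_invalid_input")
  x <- audio$samples
  if (!is.null(band_hz)) {
    band <- c(max(band_hz[1], 1e-3), min(band_hz[2], 0.99 * nyq))
    if (band[1] >= band[2])
      abort_canicoh("invalid pre-filter band", "canicoh_invalid_input")
    x <- butter_filtfilt(x, sr, band, "pass", 4L)
  }
  env <- Mod(hilbert_analytic(x))
  # decimate in two stages: cheap block mean to ~1 kHz keeps the low-pass
  # design well-conditioned, then filter, then final decimation
  fs <- sr
  if (fs > 2000) {
    f1 <- floor(fs / 1000)
    env <- block_decimate(env, f1)
    fs <- fs / f1
  }
  env <- butter_filtfilt(env, fs, env_lowpass_hz, "low", order)
  if (!is.null(decimate_to) && fs > decimate_to) {
    f2 <- floor(fs / decimate_to)
    if (f2 > 1) {
      env <- block_decimate(env, f2)
      fs <- fs / f2
    }
  }
  structure(list(values = pmax(env, 0), sample_rate = fs,
                 lowpass_hz = env_lowpass_hz, filter_order = order),
            class = "envelope")
}

#' Resample an envelope to a new rate
#'
#' Linear interpolation to `rate_hz` — safe because envelope content is
#' band-limited far below any practical target Nyquist. Used to align
#' stimulus envelopes with the EEG sampling rate.
#'
#' @param env an [compute_envelope()] result.
#' @param rate_hz target rate (Hz).
#' @return numeric vector of envelope values at `rate_hz`.
#' @export
envelope_at_rate <- function(env, rate_hz) {
  if (!inherits(env, "envelope"))
    abort_canicoh("`env` must be an envelope", "canicoh_invalid_input")
  stopifnot_scalar_num(rate_hz, "rate_hz", positive = TRUE)
  resample_linear(env$values, env$sample_rate, rate_hz)
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %.3f s @ %g Hz (low-pass %g Hz, order %d)\n",
              length(x$values) / x$sample_rate, x$sample_rate,
              x$lowpass_hz, x$filter_order))
  invisible(x)
}

#' Peak modulation frequency (vocal rate) of an envelope
#'
#' Removes the envelope mean, decomposes it with Morlet wavelets on a fine
#' frequency grid, time-averages the power, and returns the frequency of
#' the highest peak inside the search range. Ties break toward the lower
#' frequency (the grid is scanned upward).
#'
#' @param env an [compute_envelope()] result.
#' @param search_range_hz length-2 search range (Hz).
#' @param grid_hz wavelet frequency grid; default 0.5-20 Hz in 0.05 steps.
#' @param n_cycles Morlet width (cycles), default 6.
#' @return an object of class `rhythm_estimate`: `peak_hz`, `freqs_hz`,
#'   `power`, `search_range_hz`.
#' @export
envelope_rate <- function(env, search_range_hz = c(0.5, 10),
                          grid_hz = seq(0.5, 20, by = 0.05), n_cycles = 6) {
  if (!inherits(env, "envelope"))
    abort_canicoh("`env` must be an envelope", "canicoh_invalid_input")
  dur <- length(env$values) / env$sample_rate
  if (dur < 2 / search_range_hz[1])
    abort_canicoh(
      "envelope shorter than 2 cycles of the lowest search frequency",
      "canicoh_insufficient_duration")
  v <- env$values - mean(env$values)
  if (stats::sd(v) < 1e-12 * max(abs(env$values), 1e-300) ||
      all(v == 0))
    abort_canicoh("flat envelope: no modulation peak", "canicoh_no_peak")
  W <- morlet_cwt(v, env$sample_rate, grid_hz, n_cycles = n_cycles)
  pow <- rowMeans(Mod(W)^2)
  sel <- grid_hz >= search_range_hz[1] & grid_hz <= search_range_hz[2]
  if (!any(sel))
    abort_canicoh("search range outside the frequency grid",
                  "canicoh_invalid_argument")
  peak <- grid_hz[sel][which.max(pow[sel])]
  structure(list(peak_hz = peak, freqs_hz = grid_hz, power = pow,
                 search_range_hz = search_range_hz),
            class = "rhythm_estimate")
}

#' @export
print.rhythm_estimate <- function(x, ...) {
  cat(sprintf("<rhythm_estimate> peak %.2f Hz (search %g-%g Hz)\n",
              x$peak_hz, x$search_range_hz[1], x$search_range_hz[2]))
  invisible(x)
}

#' Dominant acoustic frequency
#'
#' Arg-max of the time-averaged (Welch) magnitude spectrum inside the
#' analysis band; the default 50 Hz - 2 kHz band matches single-vocalization
#' analysis where the fundamental is not reliably trackable.
#'
#' @param audio an [audio_seq] of at least 100 ms.
#' @param band_hz length-2 analysis band (Hz).
#' @return dominant frequency (Hz).
#' @export
dominant_frequency <- function(audio, band_hz = c(50, 2000)) {
  if (!inherits(audio, "audio_seq"))
    abort_canicoh("`audio` must be an audio_seq", "canicoh_invalid_input")
  sr <- audio$sample_rate
  if (length(audio$samples) / sr < 0.1)
    abort_canicoh("audio must be at least 100 ms", "canicoh_invalid_input")
  if (max(abs(audio$samples)) == 0)
    abort_canicoh("silent input: no spectral peak", "canicoh_no_peak")
  ps <- welch_psd(audio$samples, sr)
  sel <- ps$freq >= band_hz[1] & ps$freq <= min(band_hz[2], sr / 2)
  if (!any(sel) || max(ps$power[sel]) <= 0)
    abort_canicoh("no spectral peak in band", "canicoh_no_peak")
  ps$freq[sel][which.max(ps$power[sel])]
}

#' Fundamental frequency track and summary statistics
#'
#' Frame-wise F0 by normalized autocorrelation with parabolic lag
#' interpolation and a voicing threshold; returns the mean and
#' interquartile range over voiced frames plus the frame-level track.
#'
#' @param audio an [audio_seq].
#' @param f0_range_hz length-2 F0 search range (Hz).
#' @param frame_s analysis window (s); default 40 ms.
#' @param hop_s hop (s); default 10 ms.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return an object of class `spectral_features`: `f0_mean_hz`,
#'   `f0_iqr_hz`, and a `frames` data.frame (time_s, f0_hz, voiced).
#' @export
pitch_track <- function(audio, f0_range_hz = c(75, 600), frame_s = 0.04,
                        hop_s = 0.01, voicing_threshold = 0.45) {
  if (!inherits(audio, "audio_seq"))
    abort_canicoh("`audio` must be an audio_seq", "canicoh_invalid_input")
  sr <- audio$sample_rate
  x <- audio$samples
  if (length(x) < 3 * sr / f0_range_hz[1])
    abort_canicoh("audio shorter than 3 periods of the lowest F0",
                  "canicoh_invalid_input")
  flen <- round(frame_s * sr)
  hop <- max(1L, round(hop_s * sr))
  lag_min <- max(2L, floor(sr / f0_range_hz[2]))
  lag_max <- min(flen - 2L, ceiling(sr / f0_range_hz[1]))
  starts <- seq(1L, length(x) - flen + 1L, by = hop)
  silence_floor <- 0.01 * stats::quantile(abs(x), 0.999)
  times <- f0s <- numeric(length(starts))
  voiced <- logical(length(starts))
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + flen - 1L)]
    times[i] <- (starts[i] - 1 + flen / 2) / sr
    fr <- fr - mean(fr)
    if (sqrt(mean(fr^2)) < silence_floor) next
    # normalized autocorrelation via FFT
    nf <- 2^ceiling(log2(2 * flen))
    ac <- Re(stats::fft(Mod(stats::fft(c(fr, numeric(nf - flen))))^2,
                        inverse = TRUE))[seq_len(lag_max + 1)]
    r <- ac / ac[1]
    seg <- r[(lag_min + 1):(lag_max + 1)]
    j <- which.max(seg)
    if (seg[j] < voicing_threshold) next
    lag <- lag_min + j - 1
    # parabolic interpolation around the peak
    if (lag > lag_min && lag < lag_max) {
      y1 <- r[lag]; y2 <- r[lag + 1]; y3 <- r[lag + 2]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / denom
    }
    f0s[i] <- sr / lag
    voiced[i] <- TRUE
  }
  if (!any(voiced))
    abort_canicoh("no voiced frames found", "canicoh_unvoiced_input")
  v <- f0s[voiced]
  structure(list(f0_mean_hz = mean(v),
                 f0_iqr_hz = unname(diff(stats::quantile(v, c(0.25, 0.75)))),
                 frames = data.frame(time_s = times, f0_hz = f0s,
                                     voiced = voiced)),
            class = "spectral_features")
}

#' Potential for identity coding (PIC)
#'
#' Ratio of the between-individual coefficient of variation to the mean
#' within-individual coefficient of variation of an acoustic feature.
#' Coefficients use the small-sample correction
#' CV = (SD / mean) * 100 * (1 + 1 / (4 n)), applied symmetrically to CVw
#' (n = values per individual) and CVb (n = number of individuals).
#' PIC > 1 indicates individual distinctiveness.
#'
#' @param values named list: one numeric vector of feature values per
#'   individual (>= 2 individuals, >= 2 values each, all means > 0).
#' @return an object of class `pic_result`: `cv_between`,
#'   `cv_within_by_individual`, `pic`.
#' @export
pic_index <- function(values) {
  if (!is.list(values) || length(values) < 2)
    abort_canicoh("need at least 2 individuals", "canicoh_invalid_input")
  if (any(vapply(values, length, 0L) < 2))
    abort_canicoh("each individual needs at least 2 values",
                  "canicoh_invalid_input")
  cv <- function(x) {
    m <- mean(x)
    if (m <= 0)
      abort_canicoh("feature means must be > 0", "canicoh_invalid_input")
    (stats::sd(x) / m) * 100 * (1 + 1 / (4 * length(x)))
  }
  cvw <- vapply(values, cv, 0)
  cvb <- cv(vapply(values, mean, 0))
  if (mean(cvw) == 0)
    abort_canicoh("all individuals have zero within-variance: PIC undefined",
                  "canicoh_degenerate_variance")
  structure(list(cv_between = cvb, cv_within_by_individual = cvw,
                 pic = cvb / mean(cvw)),
            class = "pic_result")
}

#' @export
print.pic_result <- function(x, ...) {
  cat(sprintf("<pic_result> PIC = %.3f (CVb %.2f%% / mean CVw %.2f%%)\n",
              x$pic, x$cv_between, mean(x$cv_within_by_individual)))
  invisible(x)
}
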