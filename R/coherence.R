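# Cerebro-acoustic coherence: frequency-resolved phase coherence between
# single-channel EEG epochs and the stimulus amplitude envelope, its
# randomized-envelope surrogate null, and band-/rate-centred summaries.

# Wavelet coefficients of an epoch_set and an envelope on a common
# decimated time grid restricted to the analysis window.
cacoh_coeffs <- function(epochs, envelope, freqs, window_s, t_step_s,
                         n_cycles) {
  sr <- epochs$sample_rate
  dec <- max(1L, round(t_step_s * sr))
  # FFT length: 5-smooth and a multiple of the decimation step, so that a
  # circular shift of the coefficient columns equals a circular shift of
  # the (zero-padded) signal exactly
  pad_len <- function(n) dec * ceiling(stats::nextn(n, c(2, 3, 5)) / dec)
  times <- epoch_times(epochs)
  t_idx_epoch <- seq(1L, ncol(epochs$trials), by = dec)
  keep_e <- times[t_idx_epoch] >= window_s[1] &
    times[t_idx_epoch] <= window_s[2]
  if (!any(keep_e))
    abort_canicoh("analysis window outside epochs",
                  "canicoh_invalid_argument")
  env_t <- (seq_along(envelope) - 1) / sr
  if (anyNA(envelope))
    abort_canicoh("envelope contains NA", "canicoh_invalid_input")
  if (max(env_t) < window_s[2])
    abort_canicoh("envelope does not cover the analysis window",
                  "canicoh_invalid_input")
  n_env_fft <- pad_len(length(envelope))
  t_idx_env <- seq(1L, n_env_fft, by = dec)  # full padded circle
  env_t_pad <- (t_idx_env - 1) / sr
  keep_y <- env_t_pad >= window_s[1] & env_t_pad <= window_s[2] &
    t_idx_env <= length(envelope)
  E <- lapply(seq_len(nrow(epochs$trials)), function(k)
    morlet_cwt(epochs$trials[k, ] - mean(epochs$trials[k, ]), sr, freqs,
               n_cycles, t_index = t_idx_epoch,
               n_fft = pad_len(ncol(epochs$trials)))[, keep_e,
                                                     drop = FALSE])
  Yfull <- morlet_cwt(envelope - mean(envelope), sr, freqs, n_cycles,
                      t_index = t_idx_env, n_fft = n_env_fft)
  list(E = E, Yfull = Yfull, ycols = which(keep_y), dec = dec)
}

#' Cerebro-acoustic coherence spectrum
#'
#' Morlet cross-spectral densities between each EEG trial and the stimulus
#' envelope are summed over the analysis time window and over trials with a
#' single normalization:
#' `C(f) = |sum S_xy| / sqrt(sum S_xx * sum S_yy)`.
#' Pooling time points and trials into one estimate is what keeps
#' single-trial coherence below 1; the self-coherence of identical signals
#' is exactly 1 and `0 <= C <= 1` always (Cauchy-Schwarz; asserted).
#'
#' @param epochs an [epoch_set] (>= 2 trials).
#' @param envelope stimulus envelope at the epoch rate, aligned to t = 0.
#' @param freqs_hz frequency grid (Hz); default 1-20 in 0.1 steps.
#' @param window_s analysis window (s) post-onset; default c(0.6, 1.3)
#'   (skips the attention-grabbing name at stream onset).
#' @param t_step_s coherence time step (s); default 0.01.
#' @param n_cycles Morlet width; default 6.
#' @return an object of class `coherence_spectrum`: `freqs_hz`, `coh`,
#'   `window_s`, `n_trials`.
#' @export
cacoh_spectrum <- function(epochs, envelope,
                           freqs_hz = seq(1, 20, by = 0.1),
                           window_s = c(0.6, 1.3), t_step_s = 0.01,
                           n_cycles = 6) {
  if (!inherits(epochs, "epoch_set"))
    abort_canicoh("`epochs` must be an epoch_set", "canicoh_invalid_input")
  if (nrow(epochs$trials) < 2)
    abort_canicoh("need at least 2 trials", "canicoh_insufficient_data")
  cc <- cacoh_coeffs(epochs, envelope, freqs_hz, window_s, t_step_s,
                     n_cycles)
  Y <- cc$Yfull[, cc$ycols, drop = FALSE]
  K <- length(cc$E)
  Sxy <- 0 + 0i; Sxx <- 0
  for (k in seq_len(K)) {
    Sxy <- Sxy + rowSums(cc$E[[k]] * Conj(Y))
    Sxx <- Sxx + rowSums(Mod(cc$E[[k]])^2)
  }
  Syy <- K * rowSums(Mod(Y)^2)
  coh <- Mod(Sxy) / sqrt(Sxx * Syy)
  stopifnot(all(coh <= 1 + 1e-9), all(coh >= 0))
  structure(list(freqs_hz = freqs_hz, coh = pmin(coh, 1),
                 window_s = window_s, n_trials = K,
                 t_step_s = t_step_s, n_cycles = n_cycles),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf(
    "<coherence_spectrum> %d freqs (%g-%g Hz), %d trials, window %g-%g s\n",
    length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz), x$n_trials,
    x$window_s[1], x$window_s[2]))
  invisible(x)
}

#' Surrogate (randomized-envelope) coherence null
#'
#' Each run re-pairs every trial with an envelope drawn at random from the
#' pool and circularly time-shifted by a random amount, then recomputes the
#' coherence spectrum; the per-frequency mean and SD over runs form the
#' chance floor. Shifts are applied in the wavelet-coefficient domain on
#' the decimated time grid — exactly equivalent to shifting the envelope
#' first, because the transform uses circular FFT convolution.
#'
#' @param epochs an [epoch_set].
#' @param envelope_pool list of envelopes (epoch rate, t = 0 aligned);
#'   >= 2 entries.
#' @param freqs_hz,window_s,t_step_s,n_cycles as in [cacoh_spectrum()].
#' @param n_runs number of randomization runs (default 100).
#' @param seed integer RNG seed.
#' @return an object of class `null_coherence`: `mean`, `sd` per frequency,
#'   `n_runs`, `seed`.
#' @export
surrogate_null <- function(epochs, envelope_pool,
                           freqs_hz = seq(1, 20, by = 0.1),
                           window_s = c(0.6, 1.3), t_step_s = 0.01,
                           n_cycles = 6, n_runs = 100, seed = 1L) {
  if (!is.list(envelope_pool) || length(envelope_pool) < 2)
    abort_canicoh("envelope pool must hold at least 2 envelopes",
                  "canicoh_invalid_input")
  cc <- cacoh_coeffs(epochs, envelope_pool[[1]], freqs_hz, window_s,
                     t_step_s, n_cycles)
  pool <- vector("list", length(envelope_pool))
  pool[[1]] <- cc$Yfull
  sr <- epochs$sample_rate
  dec <- cc$dec
  for (p in seq_along(envelope_pool)[-1]) {
    env <- envelope_pool[[p]]
    if (anyNA(env))
      abort_canicoh("envelope pool contains NA", "canicoh_invalid_input")
    n_fft <- dec * ceiling(stats::nextn(length(env), c(2, 3, 5)) / dec)
    pool[[p]] <- morlet_cwt(env - mean(env), sr, freqs_hz, n_cycles,
                            t_index = seq(1L, n_fft, by = dec),
                            n_fft = n_fft)
  }
  K <- length(cc$E)
  Sxx <- 0
  for (k in seq_len(K)) Sxx <- Sxx + rowSums(Mod(cc$E[[k]])^2)
  nw <- length(cc$ycols)
  with_seed(seed, {
    runs <- matrix(0, n_runs, length(freqs_hz))
    for (r in seq_len(n_runs)) {
      Sxy <- 0 + 0i; Syy <- 0
      for (k in seq_len(K)) {
        p <- sample.int(length(pool), 1)
        Tn <- ncol(pool[[p]])
        s <- sample.int(Tn, 1) - 1L
        cols <- ((cc$ycols - 1L + s) %% Tn) + 1L
        Yk <- pool[[p]][, cols, drop = FALSE]
        Sxy <- Sxy + rowSums(cc$E[[k]] * Conj(Yk))
        Syy <- Syy + rowSums(Mod(Yk)^2)
      }
      runs[r, ] <- Mod(Sxy) / sqrt(Sxx * Syy)
    }
    structure(list(mean = colMeans(runs), sd = apply(runs, 2, stats::sd),
                   freqs_hz = freqs_hz, n_runs = n_runs, seed = seed,
                   runs = runs),
              class = "null_coherence")
  })
}

#' Band and rate-centred coherence summary
#'
#' Arithmetic means of the coherence spectrum in the delta (1-3 Hz) and
#' theta (4-7 Hz) bands, plus the mean coherence centred on the
#' subject-specific word and syllable rates (+- 0.5 Hz, evaluated on the
#' 0.5 Hz-step subgrid).
#'
#' @param coh a [cacoh_spectrum()] result.
#' @param word_rate_hz,syll_rate_hz subject-specific stimulus rates (Hz);
#'   must lie inside the spectrum grid.
#' @param summary_step_hz grid step for the rate-centred values (0.5 Hz).
#' @param delta_hz,theta_hz band definitions.
#' @return list(delta, theta, word_coh, syll_coh), all in `[0, 1]`.
#' @export
summarize_coherence <- function(coh, word_rate_hz, syll_rate_hz,
                                summary_step_hz = 0.5,
                                delta_hz = c(1, 3), theta_hz = c(4, 7)) {
  if (!inherits(coh, "coherence_spectrum"))
    abort_canicoh("`coh` must be a coherence_spectrum",
                  "canicoh_invalid_input")
  f <- coh$freqs_hz
  band_mean <- function(b) mean(coh$coh[f >= b[1] & f <= b[2]])
  rate_mean <- function(rate) {
    if (rate < min(f) || rate > max(f))
      abort_canicoh("rate outside the coherence grid",
                    "canicoh_invalid_argument")
    on_step <- abs(f / summary_step_hz - round(f / summary_step_hz)) < 1e-9
    sel <- on_step & abs(f - rate) <= 0.5 + 1e-9
    mean(coh$coh[sel])
  }
  list(delta = band_mean(delta_hz), theta = band_mean(theta_hz),
       word_coh = rate_mean(word_rate_hz),
       syll_coh = rate_mean(syll_rate_hz))
}
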