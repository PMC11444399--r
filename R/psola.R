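# Pitch-contour remapping by phase warping, plus intensity-contour
# helpers, used by the speech-type manipulations. Contracts are
# behavioural (F0 flatness, contour correlation, duration preservation),
# not sample-exact parity with any external toolkit.

# Per-sample F0 curve from a pitch_track frame table (linear interpolation
# across voiced frames, flat extrapolation at the ends).
f0_curve <- function(frames, n, sr) {
  v <- frames[frames$voiced, , drop = FALSE]
  if (nrow(v) == 0) return(NULL)
  t <- (seq_len(n) - 1) / sr
  if (nrow(v) == 1) return(rep(v$f0_hz, n))
  stats::approx(v$time_s, v$f0_hz, xout = t, rule = 2)$y
}

#' Pitch-contour modification by phase warping
#'
#' Re-synthesizes `x` so that its fundamental follows `target_f0` by
#' time-warping: the warp `w` matches the cumulative phase of the source
#' contour to that of the target, `w = Phi_src^{-1}(Phi_tgt)`, and
#' `y(t) = x(w(t))`. Duration is preserved exactly. The warp solves
#' `w'(t) = f_tgt(t) / f_src(w(t))`, so the instantaneous fundamental of
#' the output is the target contour wherever the tracker's source contour
#' is accurate. Unlike grain-based PSOLA, the map composes cleanly: the
#' remap used after word reversal is an involution, so reversing twice
#' reconstructs the waveform up to interpolation error.
#'
#' @param x numeric waveform (assumed voiced where modification matters).
#' @param sr sampling rate (Hz).
#' @param target_f0 per-sample target F0 curve (Hz) or a scalar.
#' @param source_f0 per-sample source F0 curve (Hz), e.g. from
#'   [pitch_track()] frames; `NULL` to estimate internally.
#' @param f0_range_hz search range for the internal tracker.
#' @return modified waveform, same length as `x`.
#' @keywords internal
pitch_remap <- function(x, sr, target_f0, source_f0 = NULL,
                        f0_range_hz = c(75, 600)) {
  n <- length(x)
  if (is.null(source_f0)) {
    pt <- tryCatch(
      pitch_track(audio_seq(x, sr), f0_range_hz = f0_range_hz),
      canicoh_unvoiced_input = function(e) NULL,
      canicoh_invalid_input = function(e) NULL)
    if (is.null(pt)) return(x)  # nothing voiced to modify
    source_f0 <- f0_curve(pt$frames, n, sr)
  }
  if (length(target_f0) == 1) target_f0 <- rep(target_f0, n)
  phi_src <- cumsum(source_f0) / sr
  phi_tgt <- cumsum(target_f0) / sr
  w <- stats::approx(x = phi_src, y = seq_len(n), xout = phi_tgt,
                     rule = 2)$y
  stats::approx(x = seq_len(n), y = x, xout = w, rule = 2)$y
}

# Short-term amplitude envelope: moving RMS with `smooth_s` rectangular
# smoothing (default 10 ms).
moving_rms <- function(x, sr, smooth_s = 0.01) {
  w <- max(3L, round(smooth_s * sr))
  k <- rep(1 / w, w)
  e <- as.numeric(sqrt(pmax(stats::filter(x^2, k, sides = 2), 0) + 1e-30))
  # fill the filter's edge NAs by nearest valid value
  ok <- which(!is.na(e))
  if (length(ok)) {
    e[seq_len(ok[1] - 1)] <- e[ok[1]]
    e[seq(ok[length(ok)] + 1, length.out = length(e) - ok[length(ok)])] <-
      e[ok[length(ok)]]
  }
  e
}

# Gain trajectory that replaces the current intensity contour with a target
# one: g = target_env / max(current_env, eps), smoothed and clipped to
# +-max_db. eps is 1% of the current peak (avoids blow-ups at silences).
intensity_gain <- function(current_env, target_env, max_db = 12) {
  eps <- 0.01 * max(current_env)
  g <- target_env / pmax(current_env, eps)
  lim <- 10^(max_db / 20)
  pmin(pmax(g, 1 / lim), lim)
}
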