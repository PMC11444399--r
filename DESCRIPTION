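Package: canicoh
Title: Vocal Rhythm, Speech-Stimulus Manipulation, and Cerebro-Acoustic
    Coherence Analysis
Version: 0.1.0
Authors@R: person("canicoh", "developers", email = "canicoh@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative bioacoustic and electrophysiological
    studies of vocal rhythm. Estimates repetition rates of vocal sequences
    from the amplitude-envelope modulation spectrum (Hilbert envelope plus
    Morlet wavelet decomposition), extracts dominant frequency and
    fundamental-frequency statistics, and quantifies individual acoustic
    distinctiveness with the potential-for-identity-coding (PIC) ratio.
    Builds command-word stream stimuli with controlled prosody/content
    manipulations and pitch-preserving tempo changes, preprocesses EEG
    into artifact-cleaned epochs, computes time-frequency power,
    stimulus-reconstruction (lagged ridge) decoding, and cerebro-acoustic
    coherence with a randomized-envelope surrogate null. Includes seeded
    synthetic generators for call trains, word streams, envelope-locked
    EEG, and paired speech-register tables so the full pipeline is
    testable without recordings, plus the statistical layer (paired t,
    Mann-Whitney, Kruskal-Wallis/Dunn, linear mixed models) used to relate
    neural tracking to behavioural intelligibility.
License: MIT
Encoding: UTF-8
Imports:
    nlme,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
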