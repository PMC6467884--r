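Package: bbisim
Title: Simulation and Evaluation of a Collaborative SSVEP Brain-to-Brain Interface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-person brain-to-brain interface in which two
    Senders convey binary decisions through steady-state visually evoked
    potentials (SSVEP) decoded from single-channel occipital EEG, and a
    Receiver perceives those decisions as above- or below-threshold occipital
    stimulation (phosphene present or absent) before acting through the same
    SSVEP interface. Provides a synthetic EEG generator (target sinusoid in
    1/f background noise with controllable SNR), the full decoding pipeline
    (Butterworth band-limiting, 1-second epoching, Welch power at 17 versus
    15 Hz, cursor dynamics with closest-side fallback), the two-round
    Tetris-like trial protocol with a forced-error reliability manipulation,
    a PEST-calibrated simulated stimulation channel, trust-learning agent
    models, and the evaluation suite: accuracy with exact binomial tests,
    single-operating-point ROC/AUC, plug-in mutual information with a
    small-sample bias approximation, and block-wise reliability-learning
    trend analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
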