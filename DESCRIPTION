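Package: optolfp
Title: Quantification of Optogenetic Silencing in Long-Term LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-term (multi-hour) local field
    potential (LFP) recordings with intermittent optogenetic stimulation:
    line-length magnitude quantification with hour-wise baseline
    subtraction, pulse-triggered before/after response analysis against a
    time-matched pre-stimulation baseline, Welch band-power (delta, theta,
    beta, gamma) and spectrogram computation, deterministic epileptiform
    spike/burst detection with spike-load classification and the burst
    ratio, and the accompanying statistical battery (one-sample and paired
    t, repeated-measures ANOVA with Tukey or Dunnett post hoc, Friedman and
    Kruskal-Wallis with Dunn post hoc, Pearson correlation). Includes a
    synthetic two-channel LFP generator (1/f background, band-limited
    oscillators, hour-scale habituation, pulse-locked multiplicative
    suppression or enhancement, interictal bursts, generalized seizures)
    with ground truth, plus 16-bit EDF and events-CSV I/O, so the whole
    pipeline is verifiable without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
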