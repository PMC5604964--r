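Package: ifseg
Title: Syllable and Initial/Final Segmentation of Mandarin Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic two-stage segmentation of Mandarin speech recordings
    into syllables and then into initial/final (I/F) units, designed to stay
    robust on pathological (cleft-palate) speech. Stage one locates words on a
    smoothed short-time logarithmic energy contour with a two-threshold rule,
    refines word boundaries with zero-crossing-rate jump points, and splits
    multi-syllable words at energy-contour valleys. Stage two classifies each
    syllable's initial as quasi-unvoiced or quasi-voiced from its early
    zero-crossing rates and locates the I/F boundary with a branch-specific
    rough-plus-refine procedure (level-1 Daubechies-2 wavelet product for
    quasi-unvoiced initials, band-limited autocorrelation peak counts for
    quasi-voiced ones). Includes a seeded generator of annotated synthetic
    utterances, evaluation metrics (boundary-tolerance accuracies and time
    error statistics), WAV input, and Audacity label / Praat TextGrid output.
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
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
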