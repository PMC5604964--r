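# ifseg

Automatic two-stage segmentation of Mandarin speech into syllables and then
into **initial/final (I/F)** units, built to stay robust on pathological
(cleft-palate) speech, where articulation disorders blur the usual
voiced/unvoiced cues. A Mandarin syllable is an (optional, consonantal)
initial followed by a (vocalic, always voiced) final; resonance disorders
show up on finals and voiced initials, articulation disorders on unvoiced
initials, so the I/F boundary is the minimal unit any clinical analysis of
such speech needs. The package is aimed at speech scientists and clinical
speech-signal-processing pipelines that need training-free, interpretable
segmentation of short recorded utterances.

## The method

**Stage 1 — syllable extraction.** Frames of 20 ms (50% overlap) give the
short-time logarithmic energy `L_i = lg(E_i + α) − lg α` with
`E_i = Σ_n x_i²(n)` and `α = 5·10⁵`. The contour is median-smoothed,
min-max-normalized to `L′`, and a two-threshold rule (`T₁ = 0.05`,
`T₂ = 0.1`) marks candidate words where `L′` rises through `T₁`; candidates
whose maximum never reaches `T₂`, or whose `T₂`-span is shorter than 2
frames, are discarded as silence/noise. Each rough word boundary is refined
inside a 40 ms window by the jump point (largest first difference) of a
median-smoothed 5 ms zero-crossing-rate track. Multi-syllable words are
split at the energy valley between adjacent `L′` peaks (convex-hull
analysis).

**Stage 2 — I/F segmentation.** Each syllable's initial is classified from
the maximum zero-crossing count `z` of its first five 20 ms frames (46.7 ms
span): `max(z) > 50` → *quasi-unvoiced*, otherwise *quasi-voiced* — acoustic
classes, not phonological ones, because pathology can flip voicing cues.

* *Quasi-unvoiced branch*: a level-1 Daubechies-2 wavelet decomposition
  yields approximation × detail products `C`; their short-time absolute sums
  `M_i = Σ_k |C_i(k)|` (max-normalized) form a contour that is high over the
  noise-like initial and low over the harmonic final. The first intersection
  of `M` with `T₃ = 0.005` — or, when the noise floor keeps `M` away from
  that level, the largest drop of the smoothed contour — is the rough
  boundary, then ZCR-refined in a 40 ms window.
* *Quasi-voiced branch*: the syllable is band-passed to 50–800 Hz, and the
  per-frame count of short-time autocorrelation peaks (20 ms frames,
  two-thirds overlap) forms `N_t`; its jump point within the first 250 ms
  (initials last ≲ 200 ms) is the rough boundary, refined by per-5 ms
  waveform peak counts `N_a` in a 40 ms window.

Evaluation follows the field's conventions: a syllable is correctly
extracted when both boundaries shift by less than 20 ms
(`P_S = N_S / N_SA`), and I/F accuracy `P_t` is the share of boundaries
within `t ∈ {10, 20, 30}` ms, with mean/sd time errors reported per class.

A seeded generator (`synth_utterance()`) produces annotated Mandarin-like
utterances — fricative-like noise initials, sonorant initials, glottal
pulse-train finals with formants, known boundary times, controlled SNR — so
every stage is testable without clinical data.

## Worked example

```r
library(ifseg)

u   <- synth_utterance(synth_config(n_words = 2, seed = 42))
res <- segment_speech(u$signal)          # or read_wav("utterance.wav")
res[, c("word", "syllable", "start_s", "if_boundary_s", "end_s",
        "initial", "low_confidence")]
#>   word syllable start_s if_boundary_s end_s        initial low_confidence
#> 1    1        1   0.475         0.630 0.935 quasi_unvoiced           TRUE
#> 2    2        2   1.318         1.495 1.880 quasi_unvoiced           TRUE
#> 3    2        3   1.880         1.916 2.100   quasi_voiced          FALSE

evaluate_segmentation(res, u$truth)
#> Segmentation evaluation
#>   syllable extraction: P_S = 100.00% (3 / 3)
#>   class            n   mean|e| ms  sd(e) ms   P_10%   P_20%   P_30%
#>   quasi_unvoiced   2   0.7         0.0        100.00  100.00  100.00
#>   quasi_voiced     1   30.6        NA           0.00    0.00    0.00
#>   all              3   10.7        17.3        66.67   66.67   66.67
```

Three syllables are found; each row gives the syllable interval, the I/F
boundary inside it, and the acoustic class of the initial (`low_confidence`
flags boundaries that came from a fallback rule, e.g. when the fixed `T₃`
level is never crossed under noise). The evaluation compares the result with
the generator's exact ground truth: here all three syllables are extracted
within the 20 ms tolerance, the two quasi-unvoiced I/F boundaries land
within a millisecond, and the quasi-voiced one misses by ~31 ms — the
expected ordering, since sonorant-to-vowel transitions are acoustically
blurred.

Annotations can be written as Audacity label files (`write_labels()`) or
Praat TextGrids (`write_textgrid()`); `inst/scripts/ifseg` exposes
`segment` / `synth` / `evaluate` subcommands for shell use.

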