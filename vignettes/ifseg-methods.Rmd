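---
title: "Two-stage syllable and initial/final segmentation: models, parameters, design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage syllable and initial/final segmentation: models, parameters, design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifseg)
```

## The problem and the model

A Mandarin syllable is an optional consonantal *initial* followed by a
vocalic, always-voiced *final*. In cleft-palate speech, resonance disorders
(hypernasality) live on finals and voiced initials while articulation
disorders (consonant omission, substitution, distortion) live on initials,
so initial/final (I/F) units are the smallest pieces on which a clinical
analysis can operate. Model-based segmenters (HMM/NN/GMM) need training
corpora far larger than pathological-speech collections allow, and
pathology moves the acoustics away from any corpus of typical speech. The
approach implemented here is therefore training-free and built from
interpretable frame-level features, organized as two stages with a shared
*rough-then-refine* pattern: locate a boundary coarsely on a long-frame
feature, then re-localize it inside a 40 ms window with 5 ms frames.

### Stage 1: syllable extraction

1. **Short-time logarithmic energy (STLE).** With 20 ms frames and 50%
   overlap, `L_i = log10(E_i + alpha) - log10(alpha)`,
   `E_i = sum(x_i^2)`. The additive constant `alpha = 5e5` compresses the
   dynamic range so silence, noise floor and speech separate on one scale;
   `L_i` is zero for digital silence and grows monotonically with energy.
2. **Smoothing and normalization.** The contour is median-smoothed and
   min-max-normalized to `L'` in [0, 1], making the detection thresholds
   relative rather than absolute (see *Numerical choices* for the window
   and for the silence floor this requires).
3. **Two-threshold word detection.** Runs of `L' >= T1` (`T1 = 0.05`) give
   candidate words `[A, B]`; the crossings of `T2 = 0.1` inside a run give
   the inner pair `(C, D)`. A candidate is discarded when its maximum stays
   below `T2` (silence or noise bump) or when `D - C < 2` frames (too short
   to be speech).
4. **Boundary refinement.** Around each rough word boundary a 40 ms piece
   is cut, its zero-crossing rate computed on 5 ms frames (50% overlap),
   median-smoothed (window 3), and the boundary moved to the *jump point* —
   the frame at the largest absolute first difference, i.e. where the
   silence/speech ZCR regime flips. By construction the refined boundary
   stays within ±20 ms of the rough one.
5. **Convex-hull syllable splitting.** Within a word, `L'` peaks
   (prominence ≥ 0.1 on the unit scale, separation ≥ 60 ms) anchor
   syllables; the contour minimum between two adjacent peaks is the
   internal boundary.

### Stage 2: I/F segmentation

Syllables are first classified by the maximum zero-crossing count of their
first five 20 ms frames, laid out to span 46.7 ms — a stretch that belongs
to the initial given Mandarin initial durations (≲ 200 ms). Counts above 50
mean noise-like (*quasi-unvoiced*) initials, the rest *quasi-voiced*. The
"quasi" prefix is deliberate: these are acoustic classes, because pathology
can make a phonologically voiced initial sound unvoiced and vice versa.
Classification by sign changes is amplitude-invariant.

**Quasi-unvoiced branch.** A level-1 Daubechies-2 wavelet decomposition
produces approximation and detail coefficients whose element-wise product
`C` is dense and large where the signal carries simultaneous low- and
high-band content (frication) and sparse over harmonic finals, whose detail
band is nearly empty. Frame sums `M_i = sum(|C_i|)` (10 ms frames, 5 ms
hop, in the coefficient domain; max-normalized) therefore sit high over the
initial and low over the final, and the first intersection of `M` with
`T3 = 0.005` is the rough boundary. The refinement step is the same ZCR
procedure as in stage 1 — frication has a high ZCR, voicing a low one, so
the jump point lands on the voicing onset.

**Quasi-voiced branch.** Both constituents are voiced here, so the cue is
waveform shape. After band-passing to 50–800 Hz (4th-order Butterworth
applied forward-backward, so no phase shift moves the boundary), the count
of short-time autocorrelation peaks per 20 ms frame (two-thirds overlap)
forms `N_t`: few peaks for a near-sinusoidal sonorant initial, many for a
formant-rich final. After median smoothing, the largest first difference of
`N_t` within the first 250 ms is the rough boundary `p`; refinement counts
raw waveform local maxima per 5 ms frame in a 40 ms window around `p` and
takes the jump point again.

### Evaluation

`match_syllables()` pairs predictions with ground truth greedily in time
order by maximal overlap, one-to-one; a truth syllable counts as correctly
extracted when both boundary shifts are strictly below 20 ms
(`P_S = 100 * N_S / N_SA`). `score_if()` reports `P_t` for
`t ∈ {10, 20, 30}` ms (strict inequality, nested by construction) plus mean
and standard deviation of absolute and signed errors, overall and per
class. Whether a deviation statistic should summarize signed or absolute
errors is ambiguous in the field's tables, so both are emitted.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `alpha` | 5e5 | – | STLE compression constant |
| `t1`, `t2` | 0.05, 0.1 | – | word detection thresholds on `L'` |
| `t3` | 0.005 | – | level on normalized `M` |
| `zcr_threshold` | 50 | crossings/frame | quasi-class decision |
| `stle_frame_ms` / overlap | 20 / 0.5 | ms | stage-1 framing |
| `refine_window_ms` | 40 | ms | refinement piece length |
| `refine_frame_ms` / overlap | 5 / 0.5 | ms | refinement framing |
| `classify_frame_ms`, `classify_n_frames`, `classify_span_ms` | 20, 5, 46.7 | ms | classification layout |
| `voiced_band` | 50–800 | Hz | band-pass of the voiced branch |
| `smooth_window_frames` | 5 | frames | STLE median window |
| `m_frame_ms` / `m_hop_ms` | 10 / 5 | ms | framing of `M` |
| `peak_prominence`, `peak_min_sep_ms` | 0.1, 60 | –, ms | syllable peak criteria |
| `voiced_search_ms` | 250 | ms | initial-duration prior |
| `nt_median`, `na_median` | 5, 3 | frames | smoothing of `N_t`, `N_a` |
| `silence_floor` | 1e-7 | – | absolute no-speech floor on raw STLE |
| `rate` | 44100 | Hz | working sampling rate |

The fixed thresholds (`t1`, `t2`, `t3`, 50 crossings) are only meaningful
on their stated scales: `L'` and `M` are normalized, the signal is
peak-normalized on load, and ZCR counts presume 20 ms frames at 44.1 kHz —
hence every input is resampled to `rate` before feature extraction.

The classification layout deserves a note: five 20 ms frames spanning
46.7 ms implies a hop of 20/3 ms (two-thirds overlap). A one-third-overlap
reading would span 73.3 ms, which contradicts the stated span and would
reach past short initials into the final; the printed span wins and the hop
is derived from `classify_span_ms`, so both readings remain configurable.

## What the generator emulates — and what it does not

`synth_utterance()` builds 1–3-syllable words separated by 200–500 ms
silences. Per syllable:

* **finals** are glottal impulse trains (mild shimmer) driven through two
  second-order formant resonators (400–950 Hz) plus an explicit fundamental
  component — natural vowels keep waveform-sharp glottal closures (which is
  what gives the wavelet detail band its content) and strong f0 energy;
* **quasi-unvoiced initials** are 2–10 kHz band-limited noise at −7 dB RMS
  relative to the final, a typical consonant-vowel intensity ratio;
* **quasi-voiced initials** are smooth two-harmonic sonorants near vowel
  level;
* one amplitude envelope covers the whole syllable (8 ms attack, 35 ms
  decay; within-word junctions dip to a 0.25 floor rather than silence), so
  energy has a valley *between* syllables but not at the I/F joint;
* white noise is added at a configurable SNR (default 30 dB) and truth
  boundaries are recorded sample-exactly.

Clean syllables are validated against the early-frame ZCR criterion at
generation time, so fixture labels cannot disagree with their own
acoustics; a `pathological` preset deliberately overlays noise on voiced
initials to blur the voicing cue for robustness tests (and is excluded from
that validation).

The generator does **not** model tone contours, coarticulation, formant
transitions, breathiness, multiple speakers, room reverberation, or any of
the specific cleft-palate articulation substitutions. Passing tests on this
material therefore demonstrates the internal correctness and the intended
acoustic logic of the pipeline — not clinical-grade accuracy on real
pathological recordings, which can only be established against annotated
clinical data.

One consequence of realistic noise is worth stating plainly: at SNR 30 dB
the first 20 ms frame of a syllable overlaps the onset ramp, where the
waveform is noise-dominated, and a minority of voiced initials then exceed
the 50-crossing threshold end-to-end. This is the very unreliability of
voicing cues that motivates the quasi-classes; the package flags nothing
away and reports the resulting dispatch errors honestly in its end-to-end
scores, while classification consistency proper is assessed on clean
fixtures.

## Numerical choices and design decisions

* **STLE median window.** The source description of the smoothing step
  ("half the contour length") cannot be taken literally: on a 2 s utterance
  it implies a ~1 s window whose median erases any word occupying less than
  half the window — verified directly, the first word of a test utterance
  vanishes. The package uses a fixed 5-frame (50 ms) window. The choice
  between 3 and 5 was made on generator experiments: 3 preserves narrow
  junction dips but lets the energy dip at a fricative's own I/F joint
  split the syllable in two (precisely the oversegmentation a long median
  is meant to prevent); 5 suppresses that failure mode.
* **Valley location.** Median smoothing flattens the narrow energy dip at
  a syllable junction, so the minimum of the *smoothed* contour can drift
  tens of milliseconds into a following low-energy fricative. The package
  therefore uses the smoothed contour to delimit the trough between two
  peaks (all frames within 0.05 of its minimum) and the *unsmoothed*
  contour to pinpoint the valley frame inside it. The boundary is reported
  at that frame's **center**: a frame's energy summarizes its entire 20 ms
  window, and reporting the frame start would antedate every internal
  boundary by half a frame systematically. Word boundaries keep the
  start-of-frame convention, since they are subsequently ZCR-refined at
  2.5 ms hops where the bias is negligible.
* **`T3` under a noise floor.** With `M` normalized to its maximum, a noise
  floor keeps the contour's low regime well above 0.005, and the fixed
  level is then never crossed. The implementation follows the literal rule
  — first intersection of the `T3` level, from either side — and falls back
  to the largest single-frame *drop* of the median-smoothed contour within
  the 250 ms initial-duration prior. A drop (not an absolute step) is used
  because the onset attack of the initial is a rise and would otherwise
  capture the jump; the fallback is flagged `low_confidence`.
* **Zero samples in ZCR.** A zero sample takes the sign of the previous
  nonzero sample; leading zeros count no crossing. A sinusoid starting at
  exactly phase 0 therefore counts one crossing fewer than its
  period-count suggests — a documented, tested edge case.
* **Tie-breaks.** `jump_point` resolves ties at the earliest index; valley
  plateaus resolve to their middle frame; peak conflicts under the 60 ms
  separation rule keep the higher peak.
* **Degenerate inputs.** Pure or near silence (raw STLE below
  `silence_floor`; min-max normalization is scale-free and would otherwise
  amplify a noise floor into spurious words) yields an empty result, not an
  error. Constant feature tracks, all-zero wavelet products, sub-60 ms
  syllables and never-crossing contours all take explicit fallback paths
  that are flagged `low_confidence` rather than guessed silently.
* **Autocorrelation peaks** are counted with no amplitude threshold (all
  strict interior maxima at lags ≥ 1), so the count is scale-free; the
  implementation uses an FFT autocorrelation and the test suite checks it
  exactly against a direct time-domain oracle.
* **Matching rule.** Greedy in-time one-to-one matching by maximal overlap,
  no reuse. Over- or under-segmentation therefore costs accuracy through
  unmatched or displaced syllables, which is the intended penalty.

## Problem sizes

The test suite and `scripts/acceptance.R` work at sizes chosen to give
stable statistics on a single CPU: 100 seeded utterances (roughly 400
syllables) for boundary-recovery rates, 1000 clean syllables for
classification consistency, and 100 fixtures per class for branch boundary
errors. All randomness is seed-derived; identical seeds reproduce results
bit-exactly.

## Known limitations

* Internal syllable boundaries are not ZCR-refined (only word boundaries
  are), so their resolution is bounded by the 10 ms STLE hop.
* The voiced branch's accuracy degrades when initial and final have similar
  spectral shape in the 50–800 Hz band; its errors are inherently larger
  than the unvoiced branch's, and its refinement operates on small integer
  peak counts that quantize coarsely.
* The 50-crossing classification threshold presumes 44.1 kHz sampling and
  clean-ish onsets; heavy noise floors push borderline voiced initials over
  it.
* Word detection assumes words are separated by silence gaps; overlapped or
  continuous speech is out of scope, as are tone recognition and phoneme
  identity.
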