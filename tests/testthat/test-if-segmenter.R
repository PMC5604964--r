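rate <- 44100

test_that("initial classification follows the early-frame max-ZCR rule", {
  set.seed(51)
  # noise burst: noise-like initial acoustics
  uv <- audio_signal(c(synth_unvoiced_initial(80), numeric(441)), rate)
  expect_equal(classify_initial(uv)$label, "quasi_unvoiced")
  # 150 Hz harmonic: voiced acoustics
  v <- audio_signal(synth_voiced_segment(120, 150, glottal = FALSE), rate)
  expect_equal(classify_initial(v)$label, "quasi_voiced")
  # amplitude scaling cannot change the decision (sign changes only)
  expect_equal(classify_initial(audio_signal(v$samples * 0.05, rate))$label,
               "quasi_voiced")
  expect_equal(classify_initial(audio_signal(uv$samples * 0.05, rate))$label,
               "quasi_unvoiced")
  expect_error(classify_initial(audio_signal(numeric(100), rate)), "too short")
})

test_that("the decision boundary sits strictly above 50 crossings", {
  set.seed(52)
  n <- round(0.02 * rate)
  # syllables whose first frame has exactly 51 / exactly 50 sign changes
  mk <- function(crossings) {
    first <- frame_with_crossings(n, crossings)
    rest <- rep(abs(first), 3)                     # no further crossings
    audio_signal(c(first, rest), rate)
  }
  s51 <- mk(51)
  expect_equal(classify_initial(s51)$max_zcr, 51)
  expect_equal(classify_initial(s51)$label, "quasi_unvoiced")
  s50 <- mk(50)
  expect_equal(classify_initial(s50)$max_zcr, 50)
  expect_equal(classify_initial(s50)$label, "quasi_voiced")
})

test_that("classification spans 46.7 ms in five 20 ms frames", {
  cfg <- pipeline_config()
  spec <- ifseg:::.classify_spec(cfg)
  span_ms <- (cfg$classify_n_frames - 1) * spec$hop_ms + spec$frame_ms
  expect_equal(span_ms, 46.7, tolerance = 1e-3)
  expect_equal(spec$hop_ms, 20 / 3, tolerance = 1e-9)
})

test_that("quasi-unvoiced branch finds the frication/voicing boundary", {
  errs <- sapply(1:20, function(i) {
    set.seed(600 + i)
    s <- synth_syllable("quasi_unvoiced")
    r <- segment_if_unvoiced(s$signal)
    (r$refined_s - s$if_boundary_s) * 1000
  })
  expect_lt(mean(abs(errs)), 15)
  # scaling the syllable leaves the boundary unchanged (normalized M, ZCR)
  set.seed(640)
  s <- synth_syllable("quasi_unvoiced")
  r1 <- segment_if_unvoiced(s$signal)
  r2 <- segment_if_unvoiced(audio_signal(s$signal$samples * 0.3, rate))
  expect_equal(r1$refined_s, r2$refined_s)
  # all-voiced input (no unvoiced head) is flagged low-confidence
  set.seed(641)
  allv <- audio_signal(
    synth_voiced_segment(250, 180) +
      0.002 * stats::rnorm(round(0.25 * rate)), rate)
  rv <- segment_if_unvoiced(allv)
  expect_true(rv$low_confidence)
})

test_that("quasi-voiced branch finds the sonorant/vowel boundary", {
  errs <- sapply(1:20, function(i) {
    set.seed(700 + i)
    s <- synth_syllable("quasi_voiced")
    r <- segment_if_voiced(s$signal)
    (r$refined_s - s$if_boundary_s) * 1000
  })
  expect_lt(mean(abs(errs)), 30)
  # a single unchanging sinusoid has a constant peak-count track
  mono <- audio_signal(sin(2 * pi * 200 * (0:13229) / rate), rate)
  rm <- segment_if_voiced(mono)
  expect_true(rm$low_confidence)
  # mirrored structure moves the detected jump correspondingly
  set.seed(710)
  ini <- synth_voiced_segment(100, 130, glottal = FALSE, peak = 0.5)
  fin <- synth_voiced_segment(250, 150, formants_hz = c(500, 800))
  fwd <- segment_if_voiced(audio_signal(c(ini, fin), rate))
  rev_ <- segment_if_voiced(audio_signal(c(fin, ini), rate))
  expect_lt(abs(fwd$rough_s - 0.100), 0.035)
  # reversed: transition now at 250 ms (within the 250 ms search bound)
  expect_lt(abs(rev_$rough_s - 0.250), 0.035)
  # too-short syllable falls back to the duration prior
  short <- audio_signal(sin(2 * pi * 200 * (0:2204) / rate), rate)
  expect_warning(rs <- segment_if_voiced(short), "shorter")
  expect_true(rs$low_confidence)
  expect_equal(rs$refined_s, 0.25 * duration(short))
})

test_that("dispatch is total and boundaries stay inside the syllable", {
  set.seed(800)
  for (cls in c("quasi_unvoiced", "quasi_voiced")) {
    s <- synth_syllable(cls)
    ann <- segment_initial_final(s$signal, 1, 1 + duration(s$signal))
    expect_equal(ann$initial, cls)
    expect_gte(ann$if_boundary_s, ann$start_s)
    expect_lt(ann$if_boundary_s, ann$end_s)
    expect_lte(abs(ann$if_boundary_s - ann$rough_if_boundary_s), 0.020 + 1e-9)
  }
  expect_error(segment_initial_final(s$signal, 1, 0.5), "start_s < end_s")
})

test_that("full pipeline annotations satisfy the containment invariants", {
  for (sd in c(901, 902)) {
    u <- synth_utterance(synth_config(seed = sd))
    res <- segment_speech(u$signal)
    expect_gt(nrow(res), 0L)
    expect_true(all(res$start_s <= res$if_boundary_s))
    expect_true(all(res$if_boundary_s < res$end_s))
    expect_true(all(res$initial %in% c("quasi_unvoiced", "quasi_voiced")))
    # determinism, bit-exact
    expect_identical(res, segment_speech(u$signal))
  }
})
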