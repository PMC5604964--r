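rate <- 44100

lp <- function(v) feature_track(v, frame_spec(20, 10))

test_that("two-threshold detection finds plateaus and nested inner pairs", {
  c1 <- detect_word_candidates(lp(c(0, 0, 0.5, 0.5, 0)), 0.05, 0.1)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$start_frame, 3L)
  expect_equal(c1$end_frame, 4L)
  expect_equal(c1$inner_start, 3L)
  expect_equal(c1$inner_end, 4L)
  expect_equal(nrow(detect_word_candidates(lp(c(0, 0, 0, 0)), 0.05, 0.1)), 0L)
  # a peak between t1 and t2 has no inner pair
  c2 <- detect_word_candidates(lp(c(0, 0.07, 0)), 0.05, 0.1)
  expect_equal(nrow(c2), 1L)
  expect_true(is.na(c2$inner_start))
  expect_error(detect_word_candidates(lp(c(0, 2, 0)), 0.05, 0.1), "normalized")
})

test_that("pruning removes sub-threshold and too-short candidates", {
  track <- lp(c(0, 0.07, 0.07, 0, 0, 0.5, 0.5, 0.5, 0.5, 0))
  cands <- detect_word_candidates(track, 0.05, 0.1)
  expect_equal(nrow(cands), 2L)
  kept <- prune_candidates(cands, track, 0.1)
  expect_equal(nrow(kept), 1L)         # the 0.07 plateau is silence/noise
  expect_equal(kept$start_frame, 6L)
  # inner span D - C = 1 is deleted, D - C = 2 survives
  t2 <- lp(c(0, 0.07, 0.2, 0.2, 0.07, 0))
  c2 <- detect_word_candidates(t2, 0.05, 0.1)
  expect_equal(c2$inner_end - c2$inner_start, 1L)
  expect_equal(nrow(prune_candidates(c2, t2, 0.1, min_inner_frames = 2)), 0L)
  t3 <- lp(c(0, 0.07, 0.5, 0.5, 0.5, 0.07, 0))
  c3 <- detect_word_candidates(t3, 0.05, 0.1)
  expect_equal(nrow(prune_candidates(c3, t3, 0.1, min_inner_frames = 2)), 1L)
})

test_that("ZCR refinement locks onto a silence/noise edge", {
  set.seed(31)
  sig <- step_signal(edge_s = 0.1, total_s = 0.2)
  refined <- refine_boundary(sig, 0.1)
  expect_lt(abs(refined - 0.1), 0.0026)      # within one 2.5 ms hop
  # true edge displaced +10 ms from the rough guess: error shrinks below 10 ms
  refined2 <- refine_boundary(sig, 0.09)
  expect_lt(abs(refined2 - 0.1), 0.010)
  expect_gte(refined2, 0.09 - 0.020)
  expect_lte(refined2, 0.09 + 0.020)
  # featureless window: result stays put, within the +/- 20 ms bound
  flat <- audio_signal(stats::rnorm(8820) * 0.3, rate)
  r3 <- refine_boundary(flat, 0.1)
  expect_lte(abs(r3 - 0.1), 0.020)
})

test_that("valley splitting yields one syllable per energy hump", {
  hump1 <- lp(c(0, 0.2, 0.8, 1, 0.8, 0.2, 0))
  w1 <- data.frame(start_frame = 2L, end_frame = 6L)
  s1 <- split_word_into_syllables(hump1, w1, 0.01, 0.06)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$start_s, 0.01)
  expect_equal(s1$end_s, 0.06)
  # two humps separated by >= 60 ms (7 frames apart at 10 ms hop)
  v2 <- c(0, 0.2, 0.9, 1, 0.9, 0.5, 0.2, 0.5, 0.9, 1, 0.9, 0.2, 0)
  hump2 <- lp(v2)
  w2 <- data.frame(start_frame = 2L, end_frame = 12L)
  s2 <- split_word_into_syllables(hump2, w2, 0.01, 0.12)
  expect_equal(nrow(s2), 2L)
  # valley frame 7 (value 0.2): boundary at its center = 0.06 + 0.01
  expect_equal(s2$end_s[1], 0.07)
  expect_equal(s2$start_s[2], s2$end_s[1])
  # three equal humps -> 3 syllables and 2 internal boundaries
  v3 <- c(0, v2[2:6], 0.2, v2[8:11], 0.5, 0.2, 0.5, v2[3:6], 0.2, 0)
  hump3 <- lp(minmax_normalize(v3))
  w3 <- data.frame(start_frame = 2L, end_frame = length(v3) - 1L)
  s3 <- split_word_into_syllables(hump3, w3, 0.01, (length(v3) - 2) * 0.01)
  expect_equal(nrow(s3), 3L)
  expect_true(all(diff(as.vector(rbind(s3$start_s, s3$end_s))) >= 0))
})

test_that("stage 1 returns nothing for silence and near-silence", {
  expect_equal(nrow(suppressMessages(
    segment_syllables(audio_signal(numeric(44100), rate)))), 0L)
  set.seed(8)
  floorish <- audio_signal(stats::rnorm(44100) * 1e-4, rate)
  expect_equal(nrow(suppressMessages(segment_syllables(floorish))), 0L)
})

test_that("stage 1 recovers synthetic syllable boundaries within 20 ms", {
  u1 <- synth_utterance(synth_config(n_words = 1, syllables_per_word = 1,
                                     gap_ms = c(300, 300), seed = 101))
  s1 <- segment_syllables(u1$signal)
  expect_equal(nrow(s1), 1L)
  expect_lt(abs(s1$start_s - u1$truth$start_s) * 1000, 20)
  expect_lt(abs(s1$end_s - u1$truth$end_s) * 1000, 20)
  u2 <- synth_utterance(synth_config(n_words = 1, syllables_per_word = 2,
                                     seed = 102))
  s2 <- segment_syllables(u2$signal)
  expect_equal(nrow(s2), 2L)
  expect_lt(abs(s2$end_s[1] - u2$truth$end_s[1]) * 1000, 20)
})

test_that("stage 1 output is ordered, contained, and near its rough bounds", {
  for (sd in c(201, 202, 203)) {
    u <- synth_utterance(synth_config(seed = sd))
    s <- segment_syllables(u$signal)
    expect_gt(nrow(s), 0L)
    expect_true(all(s$start_s < s$end_s))
    expect_true(all(diff(as.vector(t(s[, c("start_s", "end_s")]))) >= 0))
    expect_true(all(s$start_s >= 0 & s$end_s <= duration(u$signal)))
    # refined word boundaries stay within half the refinement window
    first_of_word <- !duplicated(s$word)
    last_of_word <- !duplicated(s$word, fromLast = TRUE)
    expect_true(all(abs(s$start_s[first_of_word] -
                          s$rough_start_s[first_of_word]) <= 0.020 + 1e-9))
    expect_true(all(abs(s$end_s[last_of_word] -
                          s$rough_end_s[last_of_word]) <= 0.020 + 1e-9))
  }
})

test_that("stage 1 is deterministic and amplitude-invariant", {
  u <- synth_utterance(synth_config(seed = 77))
  a <- segment_syllables(u$signal)
  b <- segment_syllables(u$signal)
  expect_identical(a, b)
  half <- audio_signal(u$signal$samples * 0.5, rate)
  c <- segment_syllables(half)
  expect_equal(nrow(a), nrow(c))
  expect_true(all(abs(a$start_s - c$start_s) <= 0.010 + 1e-9))
  expect_true(all(abs(a$end_s - c$end_s) <= 0.010 + 1e-9))
})
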