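rate <- 44100
spec20 <- frame_spec(20, 10)

test_that("frame_signal covers the signal with hop-spaced frames and no padding", {
  s1 <- audio_signal(seq_len(882) / 1000, rate)
  expect_equal(nrow(frame_signal(s1, spec20)), 1L)
  s3 <- audio_signal(seq_len(1764), rate)
  fr <- frame_signal(s3, spec20)
  expect_equal(nrow(fr), 3L)
  expect_equal(fr[, 1], c(1, 442, 883))   # frame starts at samples 0, 441, 882
  expect_error(frame_signal(audio_signal(seq_len(881), rate), spec20),
               "too short")
})

test_that("STLE matches the log-compressed energy definition", {
  z <- stle(audio_signal(numeric(882 * 3), rate), spec20)
  expect_true(all(z$values == 0))
  L <- stle(audio_signal(rep(1, 882), rate), spec20, alpha = 5e5)
  expect_equal(L$values, 0.000765420563, tolerance = 1e-7)
  expect_error(stle(audio_signal(rep(1, 882), rate), spec20, alpha = -1),
               "alpha")
  # monotonicity: doubling amplitudes never decreases any L_i
  set.seed(11)
  x <- stats::rnorm(4410) * 0.2
  l1 <- stle(audio_signal(x, rate), spec20)$values
  l2 <- stle(audio_signal(2 * x, rate), spec20)$values
  expect_true(all(l2 >= l1))
})

test_that("median smoothing suppresses spikes, keeps constants, rejects bad windows", {
  expect_equal(median_smooth(c(3, 3, 3, 3, 3), 3), rep(3, 5))
  expect_equal(median_smooth(c(0, 0, 9, 0, 0), 3), rep(0, 5))
  expect_error(median_smooth(1:10, 4), "odd")
  expect_error(median_smooth(1:3, 5), "exceeds")
  # idempotence on piecewise-constant tracks (window 3)
  pc <- rep(c(0, 5, 1), times = c(7, 6, 8))
  once <- median_smooth(pc, 3)
  expect_equal(median_smooth(once, 3), once)
})

test_that("min-max normalization maps to [0,1] and rejects constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 0.3, 1)), c(0, 0.3, 1))
  set.seed(4)
  v <- minmax_normalize(stats::rnorm(100))
  expect_equal(range(v), c(0, 1))
  expect_error(minmax_normalize(rep(2, 10)), "constant")
})

test_that("short-time ZCR counts sign changes with the zero-sample rule", {
  alt <- audio_signal(rep(c(1, -1), 441), rate)
  z <- short_time_zcr(alt, spec20)
  expect_equal(z$values[1], 881)
  expect_equal(short_time_zcr(audio_signal(rep(0.5, 882), rate),
                              spec20)$values[1], 0)
  # 20 ms of a 1 kHz tone: 2 crossings per period x 20 periods
  tone <- audio_signal(sin(2 * pi * 1000 * (0:881) / rate + 0.3), rate)
  expect_equal(short_time_zcr(tone, spec20)$values[1], 40)
  expect_equal(zcr_oracle(tone$samples), 40)
  # phase 0 starts on an exact zero, which by the zero rule counts no crossing
  tone0 <- audio_signal(sin(2 * pi * 1000 * (0:881) / rate), rate)
  expect_equal(short_time_zcr(tone0, spec20)$values[1], 39)
})

test_that("band-pass keeps the pass band, kills the stop band, preserves zero", {
  t <- (0:8819) / rate
  rms <- function(x) sqrt(mean(x^2))
  inb <- audio_signal(sin(2 * pi * 400 * t), rate)
  out <- bandpass(inb, 50, 800)
  expect_equal(rms(out$samples) / rms(inb$samples), 1, tolerance = 0.05)
  hi <- audio_signal(sin(2 * pi * 5000 * t), rate)
  expect_lt(rms(bandpass(hi, 50, 800)$samples) / rms(hi$samples), 0.05)
  z <- bandpass(audio_signal(numeric(1000), rate), 50, 800)
  expect_true(all(z$samples == 0))
  expect_error(bandpass(inb, 800, 50), "cutoffs")
  expect_error(bandpass(inb, 50, 30000), "cutoffs")
})

test_that("wavelet product matches the direct convolution/decimation oracle", {
  set.seed(21)
  x <- stats::rnorm(64)
  w <- wavelet_product(audio_signal(x, rate))
  o <- dwt_db2_oracle(x)
  expect_equal(length(w$approx), (64 + 3) %/% 2)
  expect_equal(w$approx, o$ca, tolerance = 1e-12)
  expect_equal(w$detail, o$cd, tolerance = 1e-12)
  expect_equal(w$values, o$ca * o$cd, tolerance = 1e-12)
  expect_equal(w$decimation, 2L)
  z <- wavelet_product(audio_signal(numeric(100), rate))
  expect_true(all(z$values == 0))
  expect_error(wavelet_product(audio_signal(c(1, 2), rate)), "too short")
})

test_that("short-time |C| sums are max-normalized and scale-invariant", {
  wp <- function(values) structure(
    list(values = values, decimation = 2L, rate = 400),
    class = "wavelet_product")
  # frame of 4 coefficients at coefficient rate 200: 20 ms frames
  M <- short_time_abs_sum(wp(c(1, -1, 1, -1)), frame_spec(20, 20))
  expect_equal(M$values, 1)
  set.seed(5)
  v <- stats::rnorm(64)
  m1 <- short_time_abs_sum(wp(v), frame_spec(20, 10))$values
  m10 <- short_time_abs_sum(wp(10 * v), frame_spec(20, 10))$values
  expect_equal(m1, m10)
  expect_true(all(m1 >= 0 & m1 <= 1))
  # silence then burst: zero over silence frames, 1 at the burst peak
  sb <- c(numeric(8), rep(0.5, 4))
  ms <- short_time_abs_sum(wp(sb), frame_spec(20, 20))$values
  expect_equal(ms, c(0, 0, 1))
  expect_error(short_time_abs_sum(wp(numeric(16)), frame_spec(20, 20)),
               "zero")
})

test_that("autocorrelation peak counts follow the strict-maxima definition", {
  expect_equal(autocorr_peak_count(rep(1, 100)), 0L)
  tone <- sin(2 * pi * 200 * (0:881) / rate)
  expect_equal(autocorr_peak_count(tone), 3L)
  expect_equal(peak_count_oracle(autocorr_oracle(tone)), 3L)
  set.seed(99)
  noise <- stats::rnorm(441)
  slow <- sin(2 * pi * 200 * (0:440) / rate + 0.2)
  expect_gt(autocorr_peak_count(noise), autocorr_peak_count(slow))
  expect_error(autocorr_peak_count(c(1, 2)), "3 samples")
})

test_that("jump point is the earliest largest first difference (new-regime frame)", {
  expect_equal(jump_point(c(0, 0, 0, 5, 5)), 4L)
  expect_equal(jump_point(c(1, 1, 1, 1)), 2L)   # all ties, earliest
  expect_equal(jump_point(c(0, 2, 1, 9, 8)), 4L)
  expect_error(jump_point(5), "2 frames")
  # reversal consistency for a single-step track: the step sits between the
  # same two samples, so indices obey j_rev = n + 2 - j_fwd
  stepv <- c(0, 0, 0, 5, 5)
  expect_equal(jump_point(rev(stepv)), length(stepv) + 2L - jump_point(stepv))
})

test_that("feature tracks map frames to exact hop-multiple times", {
  tr <- feature_track(1:7, frame_spec(20, 10), origin_time = 0.25)
  expect_equal(track_times(tr), 0.25 + (0:6) * 0.01)
  expect_error(feature_track(numeric(0), spec20), "at least one")
  expect_error(feature_track(c(1, NA), spec20), "finite")
  expect_error(frame_spec(5, 10), "hop_ms")
})
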