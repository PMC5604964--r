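# Independent brute-force oracles, written from the definitions (not from the
# package's code paths) so the implementations are cross-checked against a
# second derivation.

# sign-change count with the zero rule: a zero takes the previous nonzero
# sign, leading zeros count no crossing
zcr_oracle <- function(x) {
  prev <- 0
  count <- 0L
  for (xi in x) {
    s <- if (xi > 0) 1 else if (xi < 0) -1 else prev
    if (prev != 0 && s != 0 && s != prev) count <- count + 1L
    if (s != 0) prev <- s
  }
  count
}

# plain time-domain autocorrelation over nonnegative lags
autocorr_oracle <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(l) sum(x[1:(n - l)] * x[(1 + l):n]), numeric(1))
}

# strict interior local maxima of r at lags >= 1 (r[1] is lag 0)
peak_count_oracle <- function(r) {
  count <- 0L
  for (l in 2:(length(r) - 1L))
    if (r[l - 1L] < r[l] && r[l] > r[l + 1L]) count <- count + 1L
  count
}

# level-1 Daubechies-2 decomposition from the closed-form filter taps:
# scaling filter h_k = (1+sqrt3, 3+sqrt3, 3-sqrt3, 1-sqrt3) / (4 sqrt2),
# analysis lowpass = reversed h, highpass = h with alternating signs.
# Zero-extension convolution, keep every second output (even indices).
dwt_db2_oracle <- function(x) {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  lo <- rev(h)
  hi <- h * c(1, -1, 1, -1)
  n <- length(x)
  conv1 <- function(f) {
    out <- numeric(n + 3L)
    for (k in seq_len(n + 3L)) {
      acc <- 0
      for (i in 1:4) {
        j <- k - i + 1L
        if (j >= 1L && j <= n) acc <- acc + f[i] * x[j]
      }
      out[k] <- acc
    }
    out[seq(2L, n + 3L, by = 2L)]
  }
  list(ca = conv1(lo), cd = conv1(hi))
}

# sliding median with reflected edges, by direct window extraction
median_smooth_oracle <- function(v, window) {
  k <- (window - 1L) %/% 2L
  n <- length(v)
  vp <- c(v[(k + 1L):2L], v, v[(n - 1L):(n - k)])
  vapply(seq_len(n), function(i) stats::median(vp[i:(i + 2L * k)]), numeric(1))
}

# a frame with an exact number of sign changes: +1/-1 blocks
frame_with_crossings <- function(n, crossings) {
  flips <- sort(sample(seq_len(n - 1L), crossings))
  s <- rep(1, n)
  sgn <- 1
  prev <- 0L
  out <- numeric(0)
  bounds <- c(0L, flips, n)
  for (b in seq_len(length(bounds) - 1L)) {
    out <- c(out, rep(sgn, bounds[b + 1L] - bounds[b]))
    sgn <- -sgn
  }
  out * stats::runif(n, 0.5, 1)
}

# silence -> band-noise step edge at a known time, for refinement tests
step_signal <- function(edge_s, total_s = 0.2, rate = 44100) {
  n <- round(total_s * rate)
  ne <- round(edge_s * rate)
  x <- numeric(n)
  x[(ne + 1L):n] <- stats::rnorm(n - ne) * 0.3
  audio_signal(x, rate)
}
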