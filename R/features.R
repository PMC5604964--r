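#' Frame geometry specification
#'
#' Frame and hop duration in milliseconds. Frame length in samples is
#' `round(frame_ms * rate / 1000)` and must be at least 2.
#'
#' @param frame_ms frame duration (ms).
#' @param hop_ms hop (frame advance) duration (ms); `0 < hop_ms <= frame_ms`.
#' @export
frame_spec <- function(frame_ms, hop_ms = frame_ms / 2) {
  if (!(hop_ms > 0 && hop_ms <= frame_ms))
    stop("need 0 < hop_ms <= frame_ms (got hop ", hop_ms, ", frame ", frame_ms, ")")
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms), class = "frame_spec")
}

#' Per-frame feature sequence
#'
#' One value per frame, together with its frame geometry, so frame indices
#' map back to times: frame `i` (1-based) starts at
#' `origin_time + (i - 1) * hop_ms / 1000` seconds.
#'
#' @param values numeric vector, one value per frame.
#' @param spec a [frame_spec()].
#' @param origin_time time (s) of the first frame's first sample.
#' @export
feature_track <- function(values, spec, origin_time = 0) {
  if (length(values) < 1L) stop("feature track must have at least one frame")
  if (any(!is.finite(values))) stop("feature track contains non-finite values")
  structure(list(values = as.numeric(values), spec = spec,
                 origin_time = origin_time), class = "feature_track")
}

#' Frame start times of a feature track
#' @param track a [feature_track()].
#' @return numeric vector of start times in seconds, one per frame.
#' @export
track_times <- function(track) {
  track$origin_time + (seq_along(track$values) - 1) * track$spec$hop_ms / 1000
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track: %d frames, %g/%g ms, origin %.4f s>\n",
              length(x$values), x$spec$frame_ms, x$spec$hop_ms, x$origin_time))
  invisible(x)
}

# frame length / hop in samples for a given rate
.frame_samples <- function(spec, rate) {
  N <- round(spec$frame_ms * rate / 1000)
  hop <- round(spec$hop_ms * rate / 1000)
  if (N < 2L) stop("frame length in samples must be >= 2 (got ", N, ")")
  if (hop < 1L) stop("hop length in samples must be >= 1")
  c(N = N, hop = hop)
}

#' Slice a signal into overlapping frames
#'
#' Frame `i` covers samples `[(i-1)*hop + 1, (i-1)*hop + N]`; trailing samples
#' that do not fill a complete frame are dropped (no padding).
#'
#' @param signal an [audio_signal()].
#' @param spec a [frame_spec()].
#' @return a numeric matrix with one row per frame and `N` columns.
#' @export
frame_signal <- function(signal, spec) {
  g <- .frame_samples(spec, signal$rate)
  n <- length(signal$samples)
  if (n < g["N"])
    stop("input too short: need at least ", g["N"], " samples, got ", n)
  nf <- (n - g["N"]) %/% g["hop"] + 1L
  idx <- outer((seq_len(nf) - 1L) * g["hop"], seq_len(g["N"]), `+`)
  matrix(signal$samples[idx], nrow = nf)
}

#' Short-time logarithmic energy (STLE)
#'
#' Per frame, `E_i = sum(x_i^2)` and `L_i = log10(E_i + alpha) - log10(alpha)`.
#' The additive constant `alpha` compresses the dynamic range so that speech,
#' noise and silence separate cleanly on the resulting contour; `L_i = 0` for
#' an all-zero frame and `L_i >= 0` always.
#'
#' @param signal an [audio_signal()].
#' @param spec a [frame_spec()]; default 20 ms frames with 50% overlap.
#' @param alpha positive additive constant (default `5e5`).
#' @return a [feature_track()].
#' @export
stle <- function(signal, spec = frame_spec(20, 10), alpha = 5e5) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a single positive number")
  fr <- frame_signal(signal, spec)
  E <- rowSums(fr^2)
  feature_track(log10(E + alpha) - log10(alpha), spec)
}

#' Median-smooth a feature track
#'
#' Sliding median of odd window `window`, edges handled by reflecting the
#' sequence (output length equals input length).
#'
#' @param track a [feature_track()] or plain numeric vector.
#' @param window odd positive integer, at most the track length.
#' @export
median_smooth <- function(track, window) {
  v <- if (inherits(track, "feature_track")) track$values else track
  if (window %% 2 != 1 || window < 1) stop("'window' must be a positive odd integer")
  if (window > length(v)) stop("'window' (", window, ") exceeds track length (",
                               length(v), ")")
  if (window == 1) return(track)
  k <- (window - 1L) %/% 2L
  n <- length(v)
  # reflect (without repeating the edge sample)
  vp <- c(v[(k + 1L):2L], v, v[(n - 1L):(n - k)])
  sm <- stats::runmed(vp, window, endrule = "keep")[(k + 1L):(k + n)]
  if (inherits(track, "feature_track")) {
    track$values <- sm
    track
  } else sm
}

#' Min-max normalize a feature track to \[0, 1\]
#'
#' Affine map of the values onto \[0, 1\]. A constant track carries no speech
#' dynamics and is rejected.
#'
#' @param track a [feature_track()] or numeric vector.
#' @export
minmax_normalize <- function(track) {
  v <- if (inherits(track, "feature_track")) track$values else track
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant track: no speech dynamics to normalize")
  out <- (v - lo) / (hi - lo)
  if (inherits(track, "feature_track")) { track$values <- out; track } else out
}

# sign-change count of one frame; zero samples take the previous nonzero sign,
# leading zeros count no crossing
.zcr_frame <- function(x) {
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(0L)
  # carry the last nonzero sign forward
  idx <- cumsum(nz)
  filled <- c(0, s[nz])[idx + 1L]
  sum(filled[-1L] * filled[-length(filled)] < 0)
}

#' Short-time zero-crossing rate
#'
#' Per-frame count of waveform sign changes (a raw count, not normalized by
#' frame length): high for noise-like (unvoiced) frames, low for harmonic
#' (voiced) frames. A zero sample takes the sign of the previous nonzero
#' sample, so exact zeros are not double-counted.
#'
#' @param signal an [audio_signal()].
#' @param spec a [frame_spec()]; default 5 ms frames with 50% overlap.
#' @return a [feature_track()] of integer counts.
#' @export
short_time_zcr <- function(signal, spec = frame_spec(5, 2.5)) {
  fr <- frame_signal(signal, spec)
  feature_track(apply(fr, 1L, .zcr_frame), spec)
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so the filtering does not shift boundary times.
#'
#' @param signal an [audio_signal()].
#' @param low_hz,high_hz cutoff frequencies, `0 < low_hz < high_hz < rate/2`.
#' @param order filter order (default 4).
#' @export
bandpass <- function(signal, low_hz, high_hz, order = 4) {
  nyq <- signal$rate / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("cutoffs must satisfy 0 < low < high < rate/2 (rate ", signal$rate, ")")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  audio_signal(signal::filtfilt(bf, signal$samples), signal$rate)
}

# Daubechies-2 decomposition filters (lowpass h, highpass g by QMF)
.db2_lo <- c(-0.12940952255126037, 0.22414386804201339,
             0.83651630373780790, 0.48296291314453416)
.db2_hi <- rev(.db2_lo) * c(1, -1, 1, -1)

#' Level-1 Daubechies-2 wavelet product
#'
#' Single-level discrete wavelet decomposition with the Daubechies-2 mother
#' wavelet (zero-extension full convolution, keeping every second
#' coefficient), then the element-wise product of the approximation and
#' detail coefficient vectors. The product is large only where a frame holds
#' simultaneous low- and high-band content, which separates noise-like
#' (unvoiced) stretches from harmonic (voiced) ones. The decimation factor 2
#' maps coefficient index `k` back to original sample index `~2k`.
#'
#' @param signal an [audio_signal()].
#' @return an object of class `wavelet_product` with fields `values`
#'   (the product vector C), `approx`, `detail`, `decimation` (2) and `rate`
#'   (the original sampling rate).
#' @export
wavelet_product <- function(signal) {
  x <- signal$samples
  if (length(x) < length(.db2_lo))
    stop("input too short for a level-1 Daubechies-2 decomposition (need >= ",
         length(.db2_lo), " samples, got ", length(x), ")")
  ca_full <- stats::convolve(x, rev(.db2_lo), type = "open")
  cd_full <- stats::convolve(x, rev(.db2_hi), type = "open")
  keep <- seq(2L, length(ca_full), by = 2L)
  ca <- ca_full[keep]; cd <- cd_full[keep]
  m <- min(length(ca), length(cd))
  structure(list(values = ca[seq_len(m)] * cd[seq_len(m)],
                 approx = ca[seq_len(m)], detail = cd[seq_len(m)],
                 decimation = 2L, rate = signal$rate),
            class = "wavelet_product")
}

#' Short-time absolute-amplitude sum of a wavelet product
#'
#' Frames the coefficient vector C (frame geometry interpreted in the
#' coefficient domain, i.e. at `rate / decimation`) and sums `|C|` per frame,
#' then normalizes by the maximum so the fixed threshold of the
#' quasi-unvoiced branch is amplitude-invariant. Values lie in \[0, 1\].
#'
#' @param product a [wavelet_product()].
#' @param spec a [frame_spec()]; default 10 ms frames with 5 ms hop.
#' @return a [feature_track()] whose geometry lives in original-signal time
#'   (frame `i` starts at `(i-1) * hop_ms / 1000` s of the input signal).
#' @export
short_time_abs_sum <- function(product, spec = frame_spec(10, 5)) {
  if (all(product$values == 0))
    stop("degenerate input: wavelet product is identically zero")
  coeff_rate <- product$rate / product$decimation
  csig <- audio_signal(abs(product$values), coeff_rate)
  fr <- frame_signal(csig, spec)
  M <- rowSums(fr)
  feature_track(M / max(M), spec)
}

#' Count peaks of a frame's autocorrelation
#'
#' Autocorrelation of the frame over nonnegative lags (computed via FFT),
#' then the count of strict interior local maxima (`r[l-1] < r[l] > r[l+1]`)
#' at lags >= 1. Smooth low-frequency frames give few peaks; noisy or
#' formant-rich frames give many.
#'
#' @param frame numeric amplitude vector, length >= 3.
#' @return nonnegative integer peak count.
#' @export
autocorr_peak_count <- function(frame) {
  n <- length(frame)
  if (n < 3L) stop("frame must have at least 3 samples")
  # FFT autocorrelation, zero-padded to avoid circular wrap
  nfft <- 2L^ceiling(log2(2L * n))
  sp <- stats::fft(c(frame, numeric(nfft - n)))
  r <- Re(stats::fft(Mod(sp)^2, inverse = TRUE))[seq_len(n)]
  mid <- 2L:(n - 1L)
  sum(r[mid - 1L] < r[mid] & r[mid] > r[mid + 1L])
}

#' Jump point of a feature track
#'
#' The frame where a new regime starts: with `d[i] = |track[i+1] - track[i]|`,
#' returns `argmax(d) + 1` (1-based; ties broken by the earliest index).
#' Used for boundary refinement wherever a feature contour switches level.
#'
#' @param track a [feature_track()] or numeric vector of length >= 2.
#' @return integer frame index (first frame of the new regime).
#' @export
jump_point <- function(track) {
  v <- if (inherits(track, "feature_track")) track$values else track
  if (length(v) < 2L) stop("track must have at least 2 frames")
  which.max(abs(diff(v))) + 1L
}

# strict local maxima count of a raw waveform frame (voiced-branch refinement)
.waveform_peak_count <- function(x) {
  n <- length(x)
  if (n < 3L) return(0L)
  mid <- 2L:(n - 1L)
  sum(x[mid - 1L] < x[mid] & x[mid] > x[mid + 1L])
}

# local maxima of v with prominence and minimum separation (in indices).
# Higher peaks win when two lie closer than min_sep.
.find_peaks <- function(v, prominence = 0, min_sep = 1L) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  mid <- 2L:(n - 1L)
  cand <- mid[v[mid - 1L] < v[mid] & v[mid] >= v[mid + 1L]]
  if (length(cand) == 0) return(integer(0))
  if (prominence > 0) {
    keep <- vapply(cand, function(i) {
      # walk left/right until a higher value; prominence = peak - max(valley floors)
      lo_l <- min(v[1:i]); hi_l <- if (any(v[1:i] > v[i])) {
        j <- max(which(v[1:i] > v[i])); min(v[j:i])
      } else lo_l
      lo_r <- min(v[i:n]); hi_r <- if (any(v[i:n] > v[i])) {
        j <- i - 1L + min(which(v[i:n] > v[i])); min(v[i:j])
      } else lo_r
      (v[i] - max(hi_l, hi_r)) >= prominence
    }, logical(1))
    cand <- cand[keep]
  }
  if (min_sep > 1L && length(cand) > 1L) {
    ord <- cand[order(v[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
    cand <- sort(kept)
  }
  cand
}
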