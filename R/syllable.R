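#' Detect word candidates on the normalized STLE contour
#'
#' Two-threshold rule: runs of frames where the normalized contour stays at or
#' above `t1` give the candidate start (`A`, first frame of the run) and end
#' (`B`, last frame). Within each run, frames at or above the higher
#' threshold `t2` give the inner pair (`C`, first such frame; `D`, last),
#' recorded as `NA` when the run never reaches `t2`.
#'
#' @param lprime a [feature_track()] normalized to \[0, 1\].
#' @param t1,t2 thresholds with `0 < t1 < t2 < 1`.
#' @return data.frame with columns `start_frame`, `end_frame`, `inner_start`,
#'   `inner_end` (one row per candidate, in time order); zero rows when the
#'   contour never reaches `t1`.
#' @export
detect_word_candidates <- function(lprime, t1, t2) {
  v <- lprime$values
  if (min(v) < 0 || max(v) > 1)
    stop("'lprime' must be normalized to [0, 1]; see minmax_normalize()")
  if (!(t1 > 0 && t1 < t2 && t2 < 1)) stop("need 0 < t1 < t2 < 1")
  above <- v >= t1
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                    inner_start = integer(0), inner_end = integer(0))
  for (k in runs) {
    a <- starts[k]; b <- ends[k]
    hi <- which(v[a:b] >= t2)
    out <- rbind(out, data.frame(
      start_frame = a, end_frame = b,
      inner_start = if (length(hi)) a + hi[1] - 1L else NA_integer_,
      inner_end   = if (length(hi)) a + hi[length(hi)] - 1L else NA_integer_))
  }
  out
}

#' Prune word candidates
#'
#' Deletes candidates that are silence or noise rather than speech:
#' (1) the maximum of the normalized contour over `[A, B]` is below `t2`;
#' (2) the inner-threshold span `D - C` is shorter than `min_inner_frames`.
#'
#' @param cands candidates from [detect_word_candidates()].
#' @param lprime the normalized [feature_track()] the candidates refer to.
#' @param t2 upper threshold.
#' @param min_inner_frames minimum `D - C` frame distance (default 2).
#' @return the surviving candidates, same columns, in time order.
#' @export
prune_candidates <- function(cands, lprime, t2, min_inner_frames = 2) {
  if (nrow(cands) == 0) return(cands)
  v <- lprime$values
  keep <- vapply(seq_len(nrow(cands)), function(i) {
    a <- cands$start_frame[i]; b <- cands$end_frame[i]
    if (max(v[a:b]) < t2) return(FALSE)
    ci <- cands$inner_start[i]; di <- cands$inner_end[i]
    if (is.na(ci) || (di - ci) < min_inner_frames) return(FALSE)
    TRUE
  }, logical(1))
  cands[keep, , drop = FALSE]
}

#' Refine a rough boundary with a ZCR jump point
#'
#' Extracts a `window_ms` speech piece centered on the rough boundary,
#' computes its short-time ZCR track, median-smooths it (window 3), and
#' returns the start time of the jump-point frame — the frame where the ZCR
#' regime changes, i.e. where silence meets speech (or noise-like meets
#' harmonic). The result always stays within `window_ms / 2` of the rough
#' time; a window extending past the signal is truncated.
#'
#' @param signal the full [audio_signal()].
#' @param rough_time_s rough boundary (s).
#' @param window_ms refinement window length (default 40 ms).
#' @param zcr_spec [frame_spec()] for the ZCR (default 5 ms, 50% overlap).
#' @return refined boundary time in seconds.
#' @export
refine_boundary <- function(signal, rough_time_s, window_ms = 40,
                            zcr_spec = frame_spec(5, 2.5)) {
  half <- window_ms / 2000
  dur <- duration(signal)
  lo <- max(0, rough_time_s - half)
  hi <- min(dur, rough_time_s + half)
  piece <- tryCatch(slice_signal(signal, lo, hi), error = function(e) NULL)
  g <- .frame_samples(zcr_spec, signal$rate)
  if (is.null(piece) || length(piece$samples) < 2L * g[["N"]])
    return(rough_time_s)                      # window too small to refine
  z <- short_time_zcr(piece, zcr_spec)
  if (length(z$values) < 3L) return(rough_time_s)
  zs <- median_smooth(z, 3)
  j <- jump_point(zs)
  refined <- lo + (j - 1L) * zcr_spec$hop_ms / 1000
  min(max(refined, rough_time_s - half), rough_time_s + half)
}

#' Split a word into syllables at energy-contour valleys
#'
#' Convex-hull analysis of the normalized STLE contour within a word: local
#' maxima (prominence at least `peak_prominence`, separation at least
#' `peak_min_sep_ms`) anchor the syllables; the contour minimum between two
#' adjacent peaks is the internal segmentation frame, and the start time of
#' that frame is the syllable boundary. A word with one peak (or none, e.g. a
#' flat plateau) is returned as a single syllable spanning the word.
#'
#' @param lprime normalized STLE [feature_track()] (median-smoothed).
#' @param word one-row candidate (columns `start_frame`, `end_frame`).
#' @param word_start_s,word_end_s refined outer word boundaries (s).
#' @param config a [pipeline_config()].
#' @param lraw optional unsmoothed normalized STLE track. When given, the
#'   smoothed contour locates the trough between two peaks and the raw
#'   contour pinpoints the valley frame inside it: median smoothing is
#'   needed for stable peak/threshold decisions but flattens the narrow
#'   energy dip at the true junction, which the raw contour retains.
#' @return data.frame with columns `start_s`, `end_s`, `peak_frame`.
#' @export
split_word_into_syllables <- function(lprime, word, word_start_s, word_end_s,
                                      config = pipeline_config(),
                                      lraw = NULL) {
  a <- word$start_frame; b <- word$end_frame
  v <- lprime$values[a:b]
  hop_ms <- lprime$spec$hop_ms
  min_sep <- max(1L, round(config$peak_min_sep_ms / hop_ms))
  pk <- .find_peaks(v, prominence = config$peak_prominence, min_sep = min_sep)
  if (length(pk) == 0) {
    # flat plateau: no interior peak passes the prominence rule
    pk <- which.max(v)
  }
  pk_abs <- a + pk - 1L
  if (length(pk) <= 1L)
    return(data.frame(start_s = word_start_s, end_s = word_end_s,
                      peak_frame = pk_abs[1]))
  times <- track_times(lprime)
  vraw <- if (is.null(lraw)) NULL else lraw$values[a:b]
  bounds <- numeric(length(pk) - 1L)
  for (i in seq_len(length(pk) - 1L)) {
    seg <- pk[i]:pk[i + 1L]
    # trough of the smoothed contour between the two peaks: all frames close
    # to its minimum level (contiguous around the argmin)
    m0 <- seg[which.min(v[seg])]
    tol <- 0.05
    lo <- m0; while (lo > seg[1] && v[lo - 1L] <= v[m0] + tol) lo <- lo - 1L
    hi <- m0; while (hi < seg[length(seg)] && v[hi + 1L] <= v[m0] + tol) hi <- hi + 1L
    if (is.null(vraw)) {
      vfr <- (lo + hi) %/% 2L
    } else {
      # valley = raw-contour minimum inside the trough (middle of exact ties)
      tr <- lo:hi
      r0 <- tr[which.min(vraw[tr])]
      rlo <- r0; while (rlo > lo && vraw[rlo - 1L] == vraw[r0]) rlo <- rlo - 1L
      rhi <- r0; while (rhi < hi && vraw[rhi + 1L] == vraw[r0]) rhi <- rhi + 1L
      vfr <- (rlo + rhi) %/% 2L
    }
    # a frame's energy summarizes its whole window, so the valley frame marks
    # the junction at its center; reporting the frame start would antedate
    # every internal boundary by half a frame length
    bounds[i] <- times[a + vfr - 1L] + lprime$spec$frame_ms / 2000
  }
  starts <- c(word_start_s, bounds)
  ends <- c(bounds, word_end_s)
  ok <- starts < ends
  data.frame(start_s = starts[ok], end_s = ends[ok], peak_frame = pk_abs[ok])
}

#' Stage 1: segment a recording into syllables
#'
#' Full syllable-extraction pipeline: STLE (20 ms frames, 50% overlap) ->
#' median smoothing -> min-max normalization -> two-threshold word detection
#' -> candidate pruning -> ZCR refinement of both word boundaries -> valley
#' splitting of multi-syllable words. Returns time-ordered, non-overlapping
#' syllables as half-open intervals `[start_s, end_s)`.
#'
#' @param signal an [audio_signal()] (at least 100 ms).
#' @param config a [pipeline_config()]. The signal is resampled to
#'   `config$rate` if needed.
#' @return data.frame with columns `word`, `start_s`, `end_s`, `peak_frame`,
#'   `rough_start_s`, `rough_end_s`; zero rows when no speech is found.
#' @export
segment_syllables <- function(signal, config = pipeline_config()) {
  if (duration(signal) < 0.1)
    stop("signal shorter than 100 ms; nothing to segment")
  signal <- resample_signal(signal, config$rate)
  spec <- .stle_spec(config)
  L <- stle(signal, spec, config$alpha)
  win <- min(config$smooth_window_frames,
             2L * ((length(L$values) - 1L) %/% 2L) + 1L)
  Ls <- median_smooth(L, win)
  empty <- data.frame(word = integer(0), start_s = numeric(0),
                      end_s = numeric(0), peak_frame = integer(0),
                      rough_start_s = numeric(0), rough_end_s = numeric(0))
  if (max(L$values) < config$silence_floor ||
      max(Ls$values) <= min(Ls$values)) {
    message("no speech dynamics found; returning no syllables")
    return(empty)
  }
  lprime <- minmax_normalize(Ls)
  lraw <- minmax_normalize(L)
  cands <- detect_word_candidates(lprime, config$t1, config$t2)
  cands <- prune_candidates(cands, lprime, config$t2, config$min_inner_frames)
  if (nrow(cands) == 0) {
    message("no words found above the energy thresholds")
    return(empty)
  }
  hop_s <- spec$hop_ms / 1000
  out <- empty
  for (i in seq_len(nrow(cands))) {
    w <- cands[i, ]
    rough_start <- (w$start_frame - 1L) * hop_s
    rough_end <- w$end_frame * hop_s       # start of the frame after B
    rs <- refine_boundary(signal, rough_start, config$refine_window_ms,
                          .refine_spec(config))
    re <- refine_boundary(signal, rough_end, config$refine_window_ms,
                          .refine_spec(config))
    if (re - rs < hop_s) { rs <- rough_start; re <- rough_end }
    syl <- split_word_into_syllables(lprime, w, rs, re, config, lraw = lraw)
    syl$word <- i
    syl$rough_start_s <- rough_start
    syl$rough_end_s <- rough_end
    out <- rbind(out, syl[, c("word", "start_s", "end_s", "peak_frame",
                              "rough_start_s", "rough_end_s")])
  }
  rownames(out) <- NULL
  out
}
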