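#' Classify a syllable's initial as quasi-unvoiced or quasi-voiced
#'
#' The opening stretch of a syllable belongs to its initial. The syllable is
#' framed (20 ms frames whose hop is chosen so that the first
#' `classify_n_frames` frames span `classify_span_ms`, 46.7 ms by default)
#' and the zero-crossing rates of those early frames are computed. A maximum
#' count above `zcr_threshold` marks a noise-like, quasi-unvoiced initial;
#' otherwise the initial is quasi-voiced. The "quasi" classes are acoustic,
#' not phonological: in pathological speech a phonologically voiced initial
#' can carry unvoiced acoustics and vice versa. Classification depends only
#' on sign changes, so it is invariant to amplitude scaling.
#'
#' @param syllable_signal [audio_signal()] of one syllable.
#' @param config a [pipeline_config()].
#' @return list of class `initial_type` with fields `label`
#'   (`"quasi_unvoiced"` or `"quasi_voiced"`), `max_zcr`, and `zcr` (the
#'   per-frame counts used).
#' @export
classify_initial <- function(syllable_signal, config = pipeline_config()) {
  spec <- .classify_spec(config)
  z <- short_time_zcr(syllable_signal, spec)   # errors if < one frame
  zi <- z$values[seq_len(min(config$classify_n_frames, length(z$values)))]
  mx <- max(zi)
  structure(list(
    label = if (mx > config$zcr_threshold) "quasi_unvoiced" else "quasi_voiced",
    max_zcr = mx, zcr = zi), class = "initial_type")
}

#' @export
print.initial_type <- function(x, ...) {
  cat(sprintf("<initial_type: %s (max ZCR %d over %d frames)>\n",
              x$label, as.integer(x$max_zcr), length(x$zcr)))
  invisible(x)
}

# first index where v crosses the level thr (either direction); NA if never
.first_level_crossing <- function(v, thr) {
  if (length(v) < 2L) return(NA_integer_)
  s <- sign(v - thr)
  cross <- which(s[-1L] != s[-length(s)] & s[-1L] != 0) + 1L
  on_thr <- which(s == 0)
  hits <- sort(c(cross, on_thr[on_thr > 1L]))
  if (length(hits)) hits[1] else NA_integer_
}

# fallback rough boundary when M never meets the fixed level: the frame where
# the smoothed contour takes its largest single-frame drop, i.e. where the
# dense noise-dominated product regime of the initial gives way to the sparse
# harmonic regime of the final. The onset attack of the initial is a rise,
# so it cannot capture the jump; the search obeys the same initial-duration
# prior as the quasi-voiced branch.
.m_drop_point <- function(M, config) {
  win <- min(5L, 2L * ((length(M$values) - 1L) %/% 2L) + 1L)
  v <- median_smooth(M, win)$values
  d <- -diff(v)                              # positive where M falls
  lim <- max(2L, sum(track_times(M) <= config$voiced_search_ms / 1000))
  d <- d[seq_len(min(length(d), lim - 1L))]
  which.max(d) + 1L
}

#' I/F boundary for a syllable with a quasi-unvoiced initial
#'
#' Rough step: the syllable is decomposed with a level-1 Daubechies-2 wavelet,
#' the approximation and detail coefficients are multiplied into the vector C,
#' and the short-time absolute-amplitude sums of C form the normalized
#' contour M ([short_time_abs_sum()]). The noise-like initial and the
#' harmonic final sit at different levels of M, so the first intersection
#' point of the level `t3` with M marks the rough boundary (the start time of
#' that frame, mapped back through the decimation factor). When M never
#' crosses `t3` — typical once an appreciable noise floor is present, because
#' M is normalized to its maximum — the boundary falls back to the largest
#' single-frame drop of the median-smoothed contour within the
#' initial-duration prior (`voiced_search_ms`), i.e. the point where the
#' dense noise-like product regime gives way to the sparse harmonic one, and
#' the result is flagged low-confidence.
#'
#' Refinement step: a 40 ms piece centered on the rough boundary is
#' re-examined with 5 ms ZCR frames exactly as in word-boundary refinement
#' ([refine_boundary()]); the refined time never moves more than 20 ms.
#'
#' @param syllable_signal [audio_signal()] of one syllable.
#' @param t3 threshold on normalized M (default from `config`).
#' @param config a [pipeline_config()].
#' @return list with `rough_s`, `refined_s` (seconds from syllable start) and
#'   `low_confidence` (logical).
#' @export
segment_if_unvoiced <- function(syllable_signal, t3 = NULL,
                                config = pipeline_config()) {
  if (is.null(t3)) t3 <- config$t3
  if (!(t3 > 0 && t3 < 1)) stop("'t3' must lie in (0, 1)")
  prod <- wavelet_product(syllable_signal)
  spec <- .m_spec(config)
  M <- tryCatch(short_time_abs_sum(prod, spec), error = function(e) NULL)
  dur <- duration(syllable_signal)
  if (is.null(M) || length(M$values) < 2L) {
    warning("syllable too short or silent for the wavelet-product contour; ",
            "defaulting to first frame")
    return(list(rough_s = 0, refined_s = 0, low_confidence = TRUE))
  }
  low_conf <- FALSE
  j <- .first_level_crossing(M$values, t3)
  if (is.na(j)) {
    j <- .m_drop_point(M, config)
    low_conf <- TRUE
  }
  rough <- (j - 1L) * spec$hop_ms / 1000
  rough <- min(max(rough, 0), dur)
  refined <- refine_boundary(syllable_signal, rough, config$refine_window_ms,
                             .refine_spec(config))
  refined <- min(max(refined, 0), dur)
  list(rough_s = rough, refined_s = refined, low_confidence = low_conf)
}

#' I/F boundary for a syllable with a quasi-voiced initial
#'
#' Both the initial and the final are harmonic here, so the cue is waveform
#' shape, not voicing. Rough step: the syllable is band-passed to
#' `voiced_band` (50-800 Hz), framed with 20 ms frames and two-thirds
#' overlap, and the number of autocorrelation peaks per frame forms the
#' vector `N_t`; after median smoothing, the jump point of `N_t` — its
#' largest first-difference — is the rough boundary `p`. Because Mandarin
#' initials last at most about 200 ms, the search is restricted to frames
#' starting within the first `voiced_search_ms` of the syllable.
#'
#' Refinement step: a 40 ms piece of the band-passed signal centered at `p`
#' is framed at 5 ms with 50% overlap; the per-frame counts of strict
#' waveform local maxima form `N_a`, which is median-smoothed and the jump
#' point taken as the refined boundary.
#'
#' A syllable shorter than `min_syllable_ms` (or whose tracks are degenerate)
#' gets a boundary at 25% of its length, flagged low-confidence.
#'
#' @param syllable_signal [audio_signal()] of one syllable.
#' @param config a [pipeline_config()].
#' @return list with `rough_s`, `refined_s` (seconds from syllable start) and
#'   `low_confidence`.
#' @export
segment_if_voiced <- function(syllable_signal, config = pipeline_config()) {
  dur <- duration(syllable_signal)
  fallback <- list(rough_s = 0.25 * dur, refined_s = 0.25 * dur,
                   low_confidence = TRUE)
  if (dur * 1000 < config$min_syllable_ms) {
    warning("syllable shorter than ", config$min_syllable_ms,
            " ms; defaulting the I/F boundary to 25% of its length")
    return(fallback)
  }
  bp <- bandpass(syllable_signal, config$voiced_band[1], config$voiced_band[2])
  spec <- frame_spec(config$classify_frame_ms, config$classify_frame_ms / 3)
  fr <- tryCatch(frame_signal(bp, spec), error = function(e) NULL)
  if (is.null(fr) || nrow(fr) < 3L) return(fallback)
  nt <- feature_track(apply(fr, 1L, autocorr_peak_count), spec)
  win <- min(config$nt_median, 2L * ((length(nt$values) - 1L) %/% 2L) + 1L)
  nts <- median_smooth(nt, win)
  d <- abs(diff(nts$values))
  # initial-duration prior: the boundary frame starts within the search bound
  lim <- max(2L, sum(track_times(nts) <= config$voiced_search_ms / 1000))
  d <- d[seq_len(min(length(d), lim - 1L))]
  if (all(d == 0)) {
    rough <- spec$hop_ms / 1000            # constant track: earliest tie frame
    low_conf <- TRUE
  } else {
    rough <- which.max(d) * spec$hop_ms / 1000
    low_conf <- FALSE
  }
  refined <- .refine_voiced(bp, rough, config)
  list(rough_s = min(rough, dur), refined_s = min(max(refined, 0), dur),
       low_confidence = low_conf)
}

# waveform peak-count refinement of the quasi-voiced branch
.refine_voiced <- function(bp, rough_s, config) {
  half <- config$refine_window_ms / 2000
  dur <- duration(bp)
  lo <- max(0, rough_s - half)
  hi <- min(dur, rough_s + half)
  spec <- .refine_spec(config)
  g <- .frame_samples(spec, bp$rate)
  piece <- tryCatch(slice_signal(bp, lo, hi), error = function(e) NULL)
  if (is.null(piece) || length(piece$samples) < 2L * g[["N"]]) return(rough_s)
  fr <- frame_signal(piece, spec)
  na <- vapply(seq_len(nrow(fr)), function(i) .waveform_peak_count(fr[i, ]),
               integer(1))
  if (length(na) < 3L) return(rough_s)
  win <- min(config$na_median, 2L * ((length(na) - 1L) %/% 2L) + 1L)
  nas <- median_smooth(na, win)
  j <- jump_point(nas)
  refined <- lo + (j - 1L) * spec$hop_ms / 1000
  min(max(refined, rough_s - half), rough_s + half)
}

#' Classify a syllable and locate its I/F boundary
#'
#' Dispatch point of stage 2: classifies the initial with
#' [classify_initial()], runs the matching branch
#' ([segment_if_unvoiced()] or [segment_if_voiced()]), and returns the
#' annotated syllable with rough and refined boundaries in absolute
#' (utterance) time. The boundary is clamped strictly inside the syllable.
#'
#' @param syllable_signal [audio_signal()] of the syllable.
#' @param start_s,end_s syllable bounds in absolute time (s).
#' @param config a [pipeline_config()].
#' @return one-row data.frame: `start_s`, `if_boundary_s`, `end_s`,
#'   `rough_if_boundary_s`, `initial`, `max_zcr`, `low_confidence`.
#' @export
segment_initial_final <- function(syllable_signal, start_s, end_s,
                                  config = pipeline_config()) {
  if (end_s <= start_s) stop("syllable must satisfy start_s < end_s")
  it <- classify_initial(syllable_signal, config)
  res <- if (it$label == "quasi_unvoiced")
    segment_if_unvoiced(syllable_signal, config$t3, config)
  else
    segment_if_voiced(syllable_signal, config)
  eps <- 1 / syllable_signal$rate
  clamp <- function(t) min(max(start_s + t, start_s), end_s - eps)
  data.frame(start_s = start_s,
             if_boundary_s = clamp(res$refined_s),
             end_s = end_s,
             rough_if_boundary_s = clamp(res$rough_s),
             initial = it$label,
             max_zcr = as.integer(it$max_zcr),
             low_confidence = res$low_confidence)
}

#' Full two-stage segmentation of a recording
#'
#' Runs stage 1 ([segment_syllables()]) and then stage 2
#' ([segment_initial_final()]) on every extracted syllable.
#'
#' @param signal an [audio_signal()].
#' @param config a [pipeline_config()].
#' @return data.frame with one row per syllable: `word`, `syllable`,
#'   `start_s`, `if_boundary_s`, `end_s`, `initial`, `max_zcr`,
#'   `rough_if_boundary_s`, `low_confidence`.
#' @examples
#' \donttest{
#' synth <- synth_utterance(synth_config(n_words = 1, seed = 7))
#' segment_speech(synth$signal)
#' }
#' @export
segment_speech <- function(signal, config = pipeline_config()) {
  signal <- peak_normalize(resample_signal(signal, config$rate))
  syl <- segment_syllables(signal, config)
  out <- NULL
  for (i in seq_len(nrow(syl))) {
    piece <- slice_signal(signal, syl$start_s[i], syl$end_s[i])
    row <- tryCatch(
      segment_initial_final(piece, syl$start_s[i], syl$end_s[i], config),
      error = function(e) {
        warning("I/F segmentation failed for syllable ", i, ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(row)) next
    row$word <- syl$word[i]
    row$syllable <- i
    out <- rbind(out, row)
  }
  if (is.null(out))
    return(data.frame(word = integer(0), syllable = integer(0),
                      start_s = numeric(0), if_boundary_s = numeric(0),
                      end_s = numeric(0), initial = character(0),
                      max_zcr = integer(0), rough_if_boundary_s = numeric(0),
                      low_confidence = logical(0)))
  rownames(out) <- NULL
  out[, c("word", "syllable", "start_s", "if_boundary_s", "end_s", "initial",
          "max_zcr", "rough_if_boundary_s", "low_confidence")]
}
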