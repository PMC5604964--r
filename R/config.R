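#' Pipeline configuration
#'
#' All tunable parameters of the two-stage segmentation pipeline with their
#' default values. The energy thresholds `t1`/`t2` live on the normalized
#' STLE contour, `t3` on the max-normalized wavelet-product sum, and
#' `zcr_threshold` is a raw sign-change count on a 20 ms frame at `rate` Hz
#' (which is why every input is resampled to `rate` before feature
#' extraction).
#'
#' @param rate working sampling rate in Hz.
#' @param alpha additive STLE constant.
#' @param t1,t2 lower/upper word-detection thresholds on the normalized STLE
#'   contour.
#' @param t3 threshold on the normalized wavelet-product sum M
#'   (quasi-unvoiced branch).
#' @param zcr_threshold max early-frame ZCR separating quasi-unvoiced
#'   (`> threshold`) from quasi-voiced (`<= threshold`) initials.
#' @param stle_frame_ms,stle_overlap STLE frame length (ms) and fractional
#'   overlap.
#' @param refine_window_ms length of the speech piece used for boundary
#'   refinement (the rough boundary is its center).
#' @param refine_frame_ms,refine_overlap frame length (ms) and overlap of the
#'   refinement feature (ZCR or waveform peak count).
#' @param classify_frame_ms,classify_n_frames frame length (ms) and number of
#'   early frames used by [classify_initial()].
#' @param classify_span_ms total span of the classification frames; the hop is
#'   derived so that `classify_n_frames` frames cover exactly this span
#'   (default 46.7 ms, i.e. a 20/3 ms hop).
#' @param voiced_band band-pass cutoffs (Hz) of the quasi-voiced branch.
#' @param smooth_window_frames median window (frames, odd) applied to the STLE
#'   contour before word detection.
#' @param m_frame_ms,m_hop_ms frame geometry of the wavelet-product sum M,
#'   expressed in original-signal time.
#' @param peak_prominence,peak_min_sep_ms syllable-splitting peak criteria on
#'   the normalized STLE contour.
#' @param min_inner_frames minimum inner-threshold frame span of a word
#'   candidate (pruning rule).
#' @param voiced_search_ms rough-boundary search bound of the quasi-voiced
#'   branch (initial-duration prior).
#' @param nt_median,na_median median windows (frames) for the autocorrelation
#'   peak-count track and its refinement track.
#' @param min_syllable_ms syllables shorter than this fall back to a default
#'   boundary in the quasi-voiced branch.
#' @param silence_floor absolute floor on the raw STLE maximum below which a
#'   recording is treated as containing no speech at all. Min-max
#'   normalization is scale-free, so without this floor a pure noise floor
#'   would be amplified into spurious words.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(rate = 44100,
                            alpha = 5e5,
                            t1 = 0.05,
                            t2 = 0.1,
                            t3 = 0.005,
                            zcr_threshold = 50,
                            stle_frame_ms = 20,
                            stle_overlap = 0.5,
                            refine_window_ms = 40,
                            refine_frame_ms = 5,
                            refine_overlap = 0.5,
                            classify_frame_ms = 20,
                            classify_n_frames = 5,
                            classify_span_ms = 140 / 3,
                            voiced_band = c(50, 800),
                            smooth_window_frames = 5,
                            m_frame_ms = 10,
                            m_hop_ms = 5,
                            peak_prominence = 0.1,
                            peak_min_sep_ms = 60,
                            min_inner_frames = 2,
                            voiced_search_ms = 250,
                            nt_median = 5,
                            na_median = 3,
                            min_syllable_ms = 60,
                            silence_floor = 1e-7) {
  cfg <- list(rate = rate, alpha = alpha, t1 = t1, t2 = t2, t3 = t3,
              zcr_threshold = zcr_threshold, stle_frame_ms = stle_frame_ms,
              stle_overlap = stle_overlap, refine_window_ms = refine_window_ms,
              refine_frame_ms = refine_frame_ms, refine_overlap = refine_overlap,
              classify_frame_ms = classify_frame_ms,
              classify_n_frames = classify_n_frames,
              classify_span_ms = classify_span_ms,
              voiced_band = voiced_band,
              smooth_window_frames = smooth_window_frames,
              m_frame_ms = m_frame_ms, m_hop_ms = m_hop_ms,
              peak_prominence = peak_prominence,
              peak_min_sep_ms = peak_min_sep_ms,
              min_inner_frames = min_inner_frames,
              voiced_search_ms = voiced_search_ms,
              nt_median = nt_median, na_median = na_median,
              min_syllable_ms = min_syllable_ms,
              silence_floor = silence_floor)
  .validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

.validate_config <- function(cfg) {
  stopifnot(cfg$rate > 0, cfg$alpha > 0,
            cfg$t1 > 0, cfg$t1 < cfg$t2, cfg$t2 < 1,
            cfg$t3 > 0, cfg$t3 < 1,
            cfg$zcr_threshold > 0,
            cfg$stle_frame_ms > 0, cfg$stle_overlap > 0, cfg$stle_overlap < 1,
            cfg$refine_window_ms > 0, cfg$refine_frame_ms > 0,
            cfg$classify_frame_ms > 0, cfg$classify_n_frames >= 1,
            cfg$classify_span_ms >= cfg$classify_frame_ms,
            length(cfg$voiced_band) == 2, cfg$voiced_band[1] > 0,
            cfg$voiced_band[1] < cfg$voiced_band[2],
            cfg$voiced_band[2] < cfg$rate / 2,
            cfg$smooth_window_frames %% 2 == 1, cfg$smooth_window_frames >= 1,
            cfg$m_frame_ms > 0, cfg$m_hop_ms > 0, cfg$m_hop_ms <= cfg$m_frame_ms,
            cfg$peak_prominence >= 0, cfg$peak_min_sep_ms > 0,
            cfg$min_inner_frames >= 1, cfg$voiced_search_ms > 0,
            cfg$nt_median %% 2 == 1, cfg$na_median %% 2 == 1,
            cfg$min_syllable_ms > 0, cfg$silence_floor > 0)
  invisible(cfg)
}

# frame geometries derived from a config
.stle_spec <- function(cfg) frame_spec(cfg$stle_frame_ms,
                                       cfg$stle_frame_ms * (1 - cfg$stle_overlap))
.refine_spec <- function(cfg) frame_spec(cfg$refine_frame_ms,
                                         cfg$refine_frame_ms * (1 - cfg$refine_overlap))
.classify_spec <- function(cfg) {
  hop <- if (cfg$classify_n_frames > 1)
    (cfg$classify_span_ms - cfg$classify_frame_ms) / (cfg$classify_n_frames - 1)
  else cfg$classify_frame_ms
  frame_spec(cfg$classify_frame_ms, hop)
}
.m_spec <- function(cfg) frame_spec(cfg$m_frame_ms, cfg$m_hop_ms)

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}
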