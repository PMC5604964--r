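#' Match predicted syllables to ground truth
#'
#' Greedy one-to-one matching in time order: each truth syllable is paired
#' with the unused prediction that overlaps it most (no reuse; zero-overlap
#' predictions never match). A truth syllable counts as correctly extracted
#' when its matched prediction shifts both the start and the end boundary by
#' strictly less than `tol_ms`.
#'
#' @param pred data.frame of predictions with columns `start_s`, `end_s`
#'   (time-ordered).
#' @param truth data.frame of ground truth with columns `start_s`, `end_s`.
#' @param tol_ms boundary tolerance in milliseconds (default 20).
#' @return list with `n_correct` (N_S), `n_total` (N_SA, the number of truth
#'   syllables), and `pairs`, a data.frame mapping `truth_idx` to `pred_idx`
#'   with the boundary shifts and correctness flag.
#' @export
match_syllables <- function(pred, truth, tol_ms = 20) {
  nt <- nrow(truth); np <- nrow(pred)
  pairs <- data.frame(truth_idx = integer(0), pred_idx = integer(0),
                      start_shift_ms = numeric(0), end_shift_ms = numeric(0),
                      correct = logical(0))
  used <- logical(np)
  for (i in seq_len(nt)) {
    if (np == 0) break
    ov <- pmax(0, pmin(pred$end_s, truth$end_s[i]) -
                  pmax(pred$start_s, truth$start_s[i]))
    ov[used] <- -1
    j <- which.max(ov)
    if (length(j) == 0 || ov[j] <= 0) next
    used[j] <- TRUE
    ds <- (pred$start_s[j] - truth$start_s[i]) * 1000
    de <- (pred$end_s[j] - truth$end_s[i]) * 1000
    pairs <- rbind(pairs, data.frame(
      truth_idx = i, pred_idx = j, start_shift_ms = ds, end_shift_ms = de,
      correct = abs(ds) < tol_ms && abs(de) < tol_ms))
  }
  list(n_correct = sum(pairs$correct), n_total = nt, pairs = pairs)
}

# error statistics of a vector of signed boundary errors (ms)
.err_stats <- function(err_ms, tolerances_ms) {
  n <- length(err_ms)
  p_t <- vapply(tolerances_ms,
                function(t) if (n) 100 * sum(abs(err_ms) < t) / n else NA_real_,
                numeric(1))
  names(p_t) <- paste0("p_", tolerances_ms)
  list(n = n, p_t = p_t,
       mean_abs_err_ms = if (n) mean(abs(err_ms)) else NA_real_,
       sd_abs_err_ms = if (n > 1) stats::sd(abs(err_ms)) else NA_real_,
       mean_signed_err_ms = if (n) mean(err_ms) else NA_real_,
       sd_signed_err_ms = if (n > 1) stats::sd(err_ms) else NA_real_)
}

#' Score I/F boundary predictions
#'
#' Per tolerance `t`, the accuracy is the percentage of syllables whose
#' absolute I/F boundary error is strictly below `t` milliseconds, computed
#' overall and per initial class; mean/sd of both absolute and signed errors
#' are reported alongside. Nested tolerances are monotone by construction
#' (`p_10 <= p_20 <= p_30`).
#'
#' @param pred_if_s predicted I/F boundary times (s), one per matched
#'   syllable.
#' @param truth_if_s true I/F boundary times (s), same length and order.
#' @param initial character vector of initial classes (`"quasi_unvoiced"` /
#'   `"quasi_voiced"`), same length.
#' @param tolerances_ms tolerances in ms (default 10, 20, 30).
#' @return list of class `eval_report` with elements `all`, `quasi_unvoiced`,
#'   `quasi_voiced` (each the output of the error-statistics summary) plus
#'   `n_scored`. An empty input yields a report flagged `empty = TRUE`
#'   with `NA` statistics.
#' @export
score_if <- function(pred_if_s, truth_if_s, initial,
                     tolerances_ms = c(10, 20, 30)) {
  stopifnot(length(pred_if_s) == length(truth_if_s),
            length(initial) == length(pred_if_s))
  tolerances_ms <- sort(tolerances_ms)
  err <- (pred_if_s - truth_if_s) * 1000
  rep <- list(
    all = .err_stats(err, tolerances_ms),
    quasi_unvoiced = .err_stats(err[initial == "quasi_unvoiced"], tolerances_ms),
    quasi_voiced = .err_stats(err[initial == "quasi_voiced"], tolerances_ms),
    tolerances_ms = tolerances_ms,
    n_scored = length(err),
    empty = length(err) == 0)
  class(rep) <- "eval_report"
  rep
}

#' Evaluate a full segmentation against ground truth
#'
#' Matches predicted syllables to the truth ([match_syllables()]), computes
#' the syllable extraction accuracy `P_S = 100 * N_S / N_SA`, and scores the
#' I/F boundaries of the matched syllables ([score_if()]).
#'
#' @param pred prediction data.frame with `start_s`, `end_s`,
#'   `if_boundary_s` and (optionally) `initial`.
#' @param truth ground-truth data.frame with the same columns (e.g. from
#'   [synth_utterance()]).
#' @param tol_ms syllable-matching tolerance (ms).
#' @param tolerances_ms I/F scoring tolerances (ms).
#' @return an `eval_report` with additional fields `p_s`, `n_syll_correct`,
#'   `n_syll_total`.
#' @export
evaluate_segmentation <- function(pred, truth, tol_ms = 20,
                                  tolerances_ms = c(10, 20, 30)) {
  m <- match_syllables(pred, truth, tol_ms)
  idx <- m$pairs
  has_if <- nrow(idx) > 0 && "if_boundary_s" %in% names(pred) &&
    "if_boundary_s" %in% names(truth)
  rep <- if (has_if) {
    score_if(pred$if_boundary_s[idx$pred_idx],
             truth$if_boundary_s[idx$truth_idx],
             if ("initial" %in% names(truth)) truth$initial[idx$truth_idx]
             else rep(NA_character_, nrow(idx)),
             tolerances_ms)
  } else score_if(numeric(0), numeric(0), character(0), tolerances_ms)
  rep$p_s <- if (m$n_total) 100 * m$n_correct / m$n_total else NA_real_
  rep$n_syll_correct <- m$n_correct
  rep$n_syll_total <- m$n_total
  rep$pairs <- m$pairs
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Segmentation evaluation\n")
  if (!is.null(x$p_s))
    cat(sprintf("  syllable extraction: P_S = %.2f%% (%d / %d)\n",
                x$p_s, x$n_syll_correct, x$n_syll_total))
  if (x$empty) {
    cat("  no I/F boundaries scored\n")
    return(invisible(x))
  }
  hdr <- sprintf("  %-24s %-8s %-10s %-10s %s", "class", "n", "mean|e| ms",
                 "sd(e) ms", paste(sprintf("P_%d%%", x$tolerances_ms),
                                   collapse = "  "))
  cat(hdr, "\n")
  for (cl in c("quasi_unvoiced", "quasi_voiced", "all")) {
    s <- x[[cl]]
    if (s$n == 0) next
    cat(sprintf("  %-24s %-8d %-10.1f %-10.1f %s\n", cl, s$n,
                s$mean_abs_err_ms, s$sd_signed_err_ms,
                paste(sprintf("%6.2f", s$p_t), collapse = "  ")))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output path; written atomically.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  keep <- report[c("p_s", "n_syll_correct", "n_syll_total", "n_scored",
                   "tolerances_ms", "empty")]
  for (cl in c("all", "quasi_unvoiced", "quasi_voiced"))
    keep[[cl]] <- report[[cl]][c("n", "p_t", "mean_abs_err_ms",
                                 "sd_abs_err_ms", "mean_signed_err_ms",
                                 "sd_signed_err_ms")]
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
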