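#' Write annotations as an Audacity-style label file
#'
#' Tab-separated `start<TAB>end<TAB>label` rows with 6-decimal seconds. For
#' annotated syllables (with an I/F boundary) two intervals per syllable are
#' written: `I:quasi_unvoiced` or `I:quasi_voiced`, then `F`. A plain
#' syllable table (no `if_boundary_s`) is written as `syl` intervals.
#' Overlapping intervals are refused; writing is atomic.
#'
#' @param syllables data.frame with `start_s`, `end_s` and optionally
#'   `if_boundary_s` + `initial`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(syllables, path) {
  iv <- .annotation_intervals(syllables)
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(
    data.frame(sprintf("%.6f", iv$start), sprintf("%.6f", iv$end), iv$label),
    tmp, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

.annotation_intervals <- function(syllables) {
  if (nrow(syllables) == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0)))
  s <- syllables[order(syllables$start_s), , drop = FALSE]
  if (any(s$start_s[-1] < s$end_s[-nrow(s)] - 1e-9))
    stop("overlapping syllable intervals; refusing to write annotations")
  if (all(c("if_boundary_s", "initial") %in% names(s))) {
    data.frame(
      start = as.vector(rbind(s$start_s, s$if_boundary_s)),
      end = as.vector(rbind(s$if_boundary_s, s$end_s)),
      label = as.vector(rbind(paste0("I:", s$initial), "F")))
  } else {
    data.frame(start = s$start_s, end = s$end_s, label = "syl")
  }
}

#' Read an Audacity-style label file
#'
#' Inverse of [write_labels()]: `I:*`/`F` interval pairs are folded back into
#' one row per syllable; plain labels come back as simple intervals.
#'
#' @param path label file path.
#' @return data.frame with `start_s`, `end_s` and, if I/F pairs are present,
#'   `if_boundary_s` and `initial`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("start", "end", "label"),
                      colClasses = c("numeric", "numeric", "character")),
    error = function(e) NULL)
  if (is.null(raw))
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  is_initial <- grepl("^I:", raw$label)
  if (any(is_initial)) {
    ii <- which(is_initial)
    if (any(ii == nrow(raw)) || any(raw$label[ii + 1L] != "F"))
      stop("malformed I/F label file: every I:* interval needs a following F")
    data.frame(start_s = raw$start[ii], if_boundary_s = raw$end[ii],
               end_s = raw$end[ii + 1L],
               initial = sub("^I:", "", raw$label[ii]))
  } else {
    data.frame(start_s = raw$start, end_s = raw$end, label = raw$label)
  }
}

#' Write annotations as a Praat TextGrid
#'
#' Two interval tiers: `syllable` (one interval per syllable) and
#' `initial-final` (`I:*` and `F` intervals), padded with empty intervals
#' over silence. Long (human-readable) TextGrid format; atomic write.
#'
#' @param syllables data.frame with `start_s`, `end_s`, `if_boundary_s`,
#'   `initial`.
#' @param path output path.
#' @param total_duration_s total duration of the annotated recording;
#'   defaults to the last syllable end.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(syllables, path, total_duration_s = NULL) {
  if (is.null(total_duration_s))
    total_duration_s <- if (nrow(syllables)) max(syllables$end_s) else 0
  syl_iv <- .pad_intervals(
    data.frame(start = syllables$start_s, end = syllables$end_s,
               label = "syl"), total_duration_s)
  if_iv <- .pad_intervals(.annotation_intervals(syllables), total_duration_s)
  fmt_tier <- function(name, iv) {
    c(sprintf('        name = "%s"', name),
      "        xmin = 0",
      sprintf("        xmax = %.6f", total_duration_s),
      sprintf("        intervals: size = %d", nrow(iv)),
      unlist(lapply(seq_len(nrow(iv)), function(i) c(
        sprintf("        intervals [%d]:", i),
        sprintf("            xmin = %.6f", iv$start[i]),
        sprintf("            xmax = %.6f", iv$end[i]),
        sprintf('            text = "%s"', iv$label[i])))))
  }
  lines <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             "xmin = 0", sprintf("xmax = %.6f", total_duration_s),
             "tiers? <exists>", "size = 2", "item []:",
             "    item [1]:", '        class = "IntervalTier"',
             fmt_tier("syllable", syl_iv),
             "    item [2]:", '        class = "IntervalTier"',
             fmt_tier("initial-final", if_iv))
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

# fill gaps between intervals (and at the edges) with empty-label intervals
.pad_intervals <- function(iv, total) {
  if (nrow(iv) == 0)
    return(data.frame(start = 0, end = total, label = ""))
  iv <- iv[order(iv$start), , drop = FALSE]
  out <- NULL; cur <- 0
  for (i in seq_len(nrow(iv))) {
    if (iv$start[i] > cur + 1e-9)
      out <- rbind(out, data.frame(start = cur, end = iv$start[i], label = ""))
    out <- rbind(out, iv[i, ])
    cur <- iv$end[i]
  }
  if (total > cur + 1e-9)
    out <- rbind(out, data.frame(start = cur, end = total, label = ""))
  out
}

#' Read interval tiers from a Praat TextGrid
#'
#' Minimal reader for long-format TextGrids as produced by
#' [write_textgrid()] (and by Praat itself for interval tiers).
#'
#' @param path TextGrid path.
#' @return named list of data.frames (`start_s`, `end_s`, `label`), one per
#'   interval tier.
#' @export
read_textgrid <- function(path) {
  if (!file.exists(path)) stop("TextGrid not found: ", path)
  lines <- readLines(path, warn = FALSE)
  grab <- function(pat, x) sub(paste0(".*", pat, "\\s*=\\s*"), "", x)
  tiers <- list()
  tier_name <- NULL; cur <- NULL; xmin <- NA; xmax <- NA
  for (ln in lines) {
    if (grepl("name\\s*=", ln)) {
      if (!is.null(tier_name) && !is.null(cur)) tiers[[tier_name]] <- cur
      tier_name <- gsub('"', "", grab("name", ln))
      cur <- data.frame(start_s = numeric(0), end_s = numeric(0),
                        label = character(0))
    } else if (grepl("^\\s+xmin\\s*=", ln)) {
      xmin <- as.numeric(grab("xmin", ln))
    } else if (grepl("^\\s+xmax\\s*=", ln)) {
      xmax <- as.numeric(grab("xmax", ln))
    } else if (grepl("text\\s*=", ln) && !is.null(cur)) {
      lab <- gsub('"', "", grab("text", ln))
      cur <- rbind(cur, data.frame(start_s = xmin, end_s = xmax, label = lab))
    }
  }
  if (!is.null(tier_name) && !is.null(cur)) tiers[[tier_name]] <- cur
  tiers
}
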