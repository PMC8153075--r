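#' Construct a gaze recording
#'
#' The container for one trial's (or session segment's) eye-tracker sample
#' stream: time in ms, horizontal/vertical gaze position in degrees, pupil
#' size in arbitrary units (missing during blinks). Timestamps must be
#' strictly increasing with the constant step `1000 / sampling_rate` ms.
#'
#' @param time_ms,x_deg,y_deg,pupil Equal-length sample vectors.
#' @param sampling_rate Samples per second (default 500).
#' @param session_id,trial_id Identifiers.
#' @return An object of class `gaze_recording`.
#' @export
gaze_recording <- function(time_ms, x_deg, y_deg,
                           pupil = rep(NA_real_, length(time_ms)),
                           sampling_rate = 500,
                           session_id = NA_character_, trial_id = NA) {
  n <- length(time_ms)
  stopifnot(length(x_deg) == n, length(y_deg) == n, length(pupil) == n)
  if (n >= 2) {
    steps <- diff(time_ms)
    dt <- 1000 / sampling_rate
    if (any(steps <= 0)) stop("timestamps must be strictly increasing")
    if (any(abs(steps - dt) > 1e-6))
      stop("timestamps must advance by the constant sample period")
  }
  structure(list(sampling_rate = sampling_rate,
                 samples = data.frame(time_ms = as.numeric(time_ms),
                                      x_deg = as.numeric(x_deg),
                                      y_deg = as.numeric(y_deg),
                                      pupil = as.numeric(pupil)),
                 session_id = session_id, trial_id = trial_id),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<gaze_recording %s/%s: %d samples @ %g Hz, t = [%.1f, %.1f] ms>\n",
    x$session_id, x$trial_id, nrow(s), x$sampling_rate,
    s$time_ms[1], s$time_ms[nrow(s)]))
  invisible(x)
}

#' Write a gaze recording as tab-separated text
#'
#' Deterministic, locale-independent dialect: `#`-prefixed header lines
#' (format tag, session/trial ids, sampling rate, column order), then one
#' tab-separated row per sample. Times carry 1 decimal, positions 6,
#' pupil 3; missing values are the token `NA`.
#'
#' @param recording A `gaze_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  fmt_col <- function(x, fmt) ifelse(is.na(x), "NA", sprintf(fmt, x))
  lines <- c(
    "# ternuseye-samples v1",
    sprintf("# session_id: %s", recording$session_id),
    sprintf("# trial_id: %s", recording$trial_id),
    sprintf("# sampling_rate_hz: %s", format(recording$sampling_rate)),
    "# columns: time_ms x_deg y_deg pupil",
    if (nrow(s)) paste(fmt_col(s$time_ms, "%.1f"),
                       fmt_col(s$x_deg, "%.6f"),
                       fmt_col(s$y_deg, "%.6f"),
                       fmt_col(s$pupil, "%.3f"), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a gaze recording written by [write_samples()]
#'
#' Validates the header, column order and timestamp monotonicity; malformed
#' rows and duplicated/non-monotone timestamps are reported with their line
#' number. A 3-column file lacking the pupil column is accepted with an
#' all-missing pupil channel and a warning.
#'
#' @param path Input file path.
#' @return A `gaze_recording`.
#' @export
read_samples <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || !identical(hdr, seq_along(hdr)))
    stop("malformed file: expected a leading '#' header block")
  header <- lines[hdr]
  get_field <- function(key) {
    i <- grep(paste0("^# ", key, ":"), header)
    if (!length(i)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ":"), "", header[i[1]]))
  }
  rate <- suppressWarnings(as.numeric(get_field("sampling_rate_hz")))
  if (!isTRUE(is.finite(rate)) || rate <= 0)
    stop("unknown or invalid sampling rate in header")
  cols <- strsplit(get_field("columns"), "[ \t]+")[[1]]
  if (is.na(cols[1]) || !identical(cols[1:3], c("time_ms", "x_deg", "y_deg")))
    stop("unsupported column order (need time_ms x_deg y_deg [pupil])")
  has_pupil <- length(cols) >= 4 && cols[4] == "pupil"
  if (!has_pupil)
    warning("no pupil column declared; pupil channel set to all-missing")

  body <- lines[-hdr]
  body <- body[nzchar(body)]
  n <- length(body)
  if (n == 0)
    return(gaze_recording(numeric(0), numeric(0), numeric(0), numeric(0),
                          sampling_rate = rate,
                          session_id = get_field("session_id"),
                          trial_id = get_field("trial_id")))
  ncol_expect <- 3L + has_pupil
  parts <- strsplit(body, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != ncol_expect))
    stop(sprintf("malformed row at line %d: expected %d fields, got %d",
                 length(hdr) + which(lens != ncol_expect)[1],
                 ncol_expect, lens[lens != ncol_expect][1]))
  mat <- matrix(unlist(parts), nrow = n, byrow = TRUE)
  num <- function(v) suppressWarnings(ifelse(v == "NA", NA_real_,
                                             as.numeric(v)))
  time_ms <- num(mat[, 1])
  if (anyNA(time_ms))
    stop(sprintf("malformed timestamp at line %d",
                 length(hdr) + which(is.na(time_ms))[1]))
  if (n >= 2) {
    bad <- which(diff(time_ms) <= 0)
    if (length(bad))
      stop(sprintf("non-monotone or duplicated timestamp at line %d",
                   length(hdr) + bad[1] + 1L))
  }
  gaze_recording(time_ms = time_ms, x_deg = num(mat[, 2]),
                 y_deg = num(mat[, 3]),
                 pupil = if (has_pupil) num(mat[, 4]) else rep(NA_real_, n),
                 sampling_rate = rate,
                 session_id = get_field("session_id"),
                 trial_id = suppressWarnings({
                   tid <- get_field("trial_id")
                   ti <- as.integer(tid)
                   if (is.na(ti)) tid else ti
                 }))
}

#' Detect blink intervals from the pupil channel
#'
#' Maximal runs of missing (or non-positive) pupil samples, each padded by
#' `pad_ms` on both sides; padded intervals closer than `min_gap_ms` (or
#' overlapping) are merged. Intervals are half-open `[start, end)` ms.
#'
#' @param recording A `gaze_recording` with a pupil channel.
#' @param pad_ms Padding added to each side of a raw blink run (default 50).
#' @param min_gap_ms Merge padded intervals separated by less than this
#'   (default 0: merge only on overlap/contact).
#' @return data.frame with columns `start_ms`, `end_ms`; zero rows when no
#'   blinks.
#' @export
detect_blinks <- function(recording, pad_ms = 50, min_gap_ms = 0) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  dt <- 1000 / recording$sampling_rate
  missing <- is.na(s$pupil) | s$pupil <= 0
  if (!any(missing))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  r <- rle(missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  iv <- data.frame(start_ms = s$time_ms[starts[keep]] - pad_ms,
                   end_ms = s$time_ms[ends[keep]] + dt + pad_ms)
  merge_intervals(iv, min_gap_ms)
}

# merge sorted half-open intervals whose gaps are < min_gap (<= 0 gap always
# merges)
merge_intervals <- function(iv, min_gap = 0) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$start_ms), ]
  out_s <- iv$start_ms[1]
  out_e <- iv$end_ms[1]
  for (i in 2:nrow(iv)) {
    if (iv$start_ms[i] - out_e[length(out_e)] < max(0, min_gap) + 1e-9) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end_ms[i])
    } else {
      out_s <- c(out_s, iv$start_ms[i])
      out_e <- c(out_e, iv$end_ms[i])
    }
  }
  data.frame(start_ms = out_s, end_ms = out_e)
}

#' Extract the per-trial gaze and its duration
#'
#' The "gaze" is the single fixation spanning the whole Ternus presentation:
#' the maximal interval of the recording containing
#' `[frame1 onset, frame2 offset)` that is free of saccade candidates and
#' blinks. If any saccade or blink intersects the presentation window the
#' trial is invalid with reason `no_spanning_fixation`; if the response
#' timestamp falls inside the gaze it is invalid with reason
#' `response_during_gaze`. For control trials without displayed frames the
#' nominal frame times bound the same spanning window.
#'
#' @param recording A `gaze_recording`.
#' @param trial One row of a design's trial table.
#' @param saccade_events data.frame with `onset_ms`, `offset_ms` (any
#'   supra-threshold velocity excursion, i.e. candidates before the duration
#'   filter, so large saccades also break a gaze).
#' @param blink_intervals data.frame with `start_ms`, `end_ms`.
#' @param response_time_ms Absolute response time, or `NA` to skip the
#'   response exclusion.
#' @return One-row data.frame: `trial_id`, `gaze_start_ms`, `gaze_end_ms`,
#'   `duration_ms`, `valid`, `exclusion_reason`.
#' @export
extract_gaze_duration <- function(recording, trial, saccade_events,
                                  blink_intervals, response_time_ms = NA) {
  stopifnot(inherits(recording, "gaze_recording"))
  if (is.null(trial$frame1_ms) || is.na(trial$frame1_ms) ||
      is.na(trial$frame2_ms))
    stop("trial timeline lacks the frame (or nominal frame) events")
  win_start <- trial$frame1_ms
  win_end <- trial$frame2_ms + frame_duration_ms()
  s <- recording$samples
  dt <- 1000 / recording$sampling_rate
  rec_start <- s$time_ms[1]
  rec_end <- s$time_ms[nrow(s)] + dt

  brk_s <- brk_e <- numeric(0)
  if (!is.null(saccade_events) && nrow(saccade_events)) {
    brk_s <- c(brk_s, saccade_events$onset_ms)
    brk_e <- c(brk_e, saccade_events$offset_ms)
  }
  if (!is.null(blink_intervals) && nrow(blink_intervals)) {
    brk_s <- c(brk_s, blink_intervals$start_ms)
    brk_e <- c(brk_e, blink_intervals$end_ms)
  }
  res <- function(start, end, valid, reason)
    data.frame(trial_id = trial$trial_id, gaze_start_ms = start,
               gaze_end_ms = end, duration_ms = end - start, valid = valid,
               exclusion_reason = reason, stringsAsFactors = FALSE)

  inside <- brk_s < win_end & brk_e > win_start
  if (any(inside))
    return(res(NA_real_, NA_real_, FALSE, "no_spanning_fixation"))
  before <- brk_e[brk_e <= win_start]
  after <- brk_s[brk_s >= win_end]
  gaze_start <- if (length(before)) max(rec_start, max(before)) else rec_start
  gaze_end <- if (length(after)) min(rec_end, min(after)) else rec_end
  if (!is.na(response_time_ms) &&
      response_time_ms >= gaze_start && response_time_ms < gaze_end)
    return(res(gaze_start, gaze_end, FALSE, "response_during_gaze"))
  res(gaze_start, gaze_end, TRUE, "none")
}
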