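#' Linear interpolation of blink gaps in a pupil trace
#'
#' Samples inside the blink intervals (and any additional missing samples)
#' are replaced by the straight line joining the last valid sample before
#' and the first valid sample after the gap; leading/trailing gaps are
#' filled by constant extension of the nearest valid value. Valid samples
#' are never changed.
#'
#' @param time_ms Sample times.
#' @param values Pupil values (arbitrary units), may contain `NA`.
#' @param blink_intervals data.frame with `start_ms`, `end_ms` (half-open),
#'   or `NULL` to interpolate only the already-missing samples.
#' @return The interpolated trace.
#' @export
interpolate_blinks <- function(time_ms, values, blink_intervals = NULL) {
  miss <- is.na(values)
  if (!is.null(blink_intervals) && nrow(blink_intervals))
    for (i in seq_len(nrow(blink_intervals)))
      miss <- miss | (time_ms >= blink_intervals$start_ms[i] &
                        time_ms < blink_intervals$end_ms[i])
  if (!any(miss)) return(values)
  if (all(miss)) stop("trace entirely missing")
  out <- values
  out[miss] <- stats::approx(time_ms[!miss], values[!miss],
                             xout = time_ms[miss], rule = 2)$y
  out
}

#' Z-score pupil samples over a whole session
#'
#' `z = (p - mean_session) / sd_session`, the mean and SD computed over all
#' interpolated samples of the session, removing between-session differences
#' in raw pupil units.
#'
#' @param values All (interpolated) pupil samples of the session.
#' @return List: `z` (normalized samples), `mean`, `sd`.
#' @export
normalize_session <- function(values) {
  if (anyNA(values)) stop("interpolate blinks before normalizing")
  m <- mean(values)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("zero session variance: constant or invalid pupil channel")
  list(z = (values - m) / s, mean = m, sd = s)
}

#' Cut an epoch around a lock event
#'
#' @param time_ms,values A trace.
#' @param lock_time_ms Absolute time of the lock event.
#' @param window_ms Half-open window relative to the lock event.
#' @return List: `time_ms` (relative grid), `values`.
#' @export
epoch_trace <- function(time_ms, values, lock_time_ms,
                        window_ms = c(-500, 1000)) {
  rel <- time_ms - lock_time_ms
  sel <- rel >= window_ms[1] & rel < window_ms[2]
  if (!any(sel)) stop("epoch window outside the trace extent")
  list(time_ms = rel[sel], values = values[sel])
}

#' Baseline-correct a pupil epoch
#'
#' Subtracts the mean over the half-open baseline window (default
#' `[-100, 0)` ms, the 0.1 s preceding the first frame, excluding the
#' frame-onset sample) from the whole epoch.
#'
#' @param epoch List with `time_ms` (relative grid) and `values`.
#' @param baseline_window_ms Half-open baseline window.
#' @return The corrected epoch (baseline mean exactly 0).
#' @export
baseline_correct <- function(epoch, baseline_window_ms = c(-100, 0)) {
  sel <- epoch$time_ms >= baseline_window_ms[1] &
    epoch$time_ms < baseline_window_ms[2]
  if (!any(sel)) stop("epoch does not cover the baseline window")
  epoch$values <- epoch$values - mean(epoch$values[sel])
  epoch
}

#' Two-level (participant-weighted) epoch average
#'
#' Trials are first averaged within participant, then participants averaged
#' with equal weight; the SE is computed across participants, matching
#' across-participant error reporting.
#'
#' @param epochs_by_participant List (one element per participant) of
#'   trials x time matrices on a shared grid.
#' @param time_ms The shared relative time grid.
#' @return List: `time_ms`, `mean`, `se`, `n_participants`,
#'   `participant_means` (participants x time matrix).
#' @export
epoch_average <- function(epochs_by_participant, time_ms) {
  if (!length(epochs_by_participant)) stop("no participants")
  pm <- t(vapply(epochs_by_participant, function(m) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    colMeans(m)
  }, numeric(length(time_ms))))
  n <- nrow(pm)
  list(time_ms = time_ms, mean = colMeans(pm),
       se = if (n > 1) apply(pm, 2, stats::sd) / sqrt(n)
            else rep(NA_real_, ncol(pm)),
       n_participants = n, participant_means = pm)
}
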