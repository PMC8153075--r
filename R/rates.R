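#' Per-trial event-onset raster
#'
#' Bins microsaccade onsets into the sample grid relative to a lock event
#' (first frame, second frame or first beep). Bin `[t, t + dt)` of a trial is
#' 1 iff an onset falls in it.
#'
#' @param events data.frame with `trial_id` and `onset_ms` (absolute times).
#' @param trials Design trial table (provides the lock-event times).
#' @param lock `"frame1"`, `"frame2"` or `"beep1"`.
#' @param window_ms Epoch window relative to the lock event (half-open),
#'   default `c(-500, 1000)`.
#' @param sampling_rate Samples per second (default 500).
#' @return Binary matrix, trials x bins; `attr(, "time_ms")` holds the bin
#'   left edges; rownames are trial ids.
#' @export
event_raster <- function(events, trials, lock = c("frame1", "frame2", "beep1"),
                         window_ms = c(-500, 1000), sampling_rate = 500) {
  lock <- match.arg(lock)
  lock_col <- paste0(lock, "_ms")
  if (!lock_col %in% names(trials)) stop("unknown lock event column")
  lock_t <- trials[[lock_col]]
  if (anyNA(lock_t))
    stop(sprintf("lock event '%s' missing from trial(s) %s", lock,
                 paste(utils::head(trials$trial_id[is.na(lock_t)], 3),
                       collapse = ", ")))
  dt <- 1000 / sampling_rate
  grid <- seq(window_ms[1], window_ms[2] - dt, by = dt)
  raster <- matrix(0L, nrow = nrow(trials), ncol = length(grid),
                   dimnames = list(trials$trial_id, NULL))
  if (nrow(events)) {
    idx <- match(events$trial_id, trials$trial_id)
    rel <- events$onset_ms - lock_t[idx]
    bin <- floor((rel - window_ms[1]) / dt) + 1L
    ok <- !is.na(idx) & bin >= 1L & bin <= length(grid)
    raster[cbind(idx[ok], bin[ok])] <- 1L
  }
  attr(raster, "time_ms") <- grid
  raster
}

#' Causal smoothing kernel for event rates
#'
#' Discretizes `w(tau) = alpha^2 * tau * exp(-alpha * tau)` on the sample
#' grid for `tau >= 0`, truncated at `support_ms` and renormalized to unit
#' sum, so convolution conserves total event mass. With the default decay
#' `alpha = 1/20` per ms the kernel peaks at `tau = 1/alpha = 20 ms` and is
#' strictly causal: `w(0) = 0` and no weight at negative lags.
#'
#' @param alpha Decay parameter, 1/ms (default 1/20).
#' @param support_ms Truncation length, ms (default 200; must be at least
#'   `5 / alpha`).
#' @param step_ms Grid step, ms (the sample period; default 2).
#' @return Numeric kernel vector (lag 0, step, 2*step, ...), class
#'   `rate_kernel` with `alpha` and `step_ms` attributes.
#' @export
smoothing_kernel <- function(alpha = 1 / 20, support_ms = 200, step_ms = 2) {
  stopifnot(alpha > 0, step_ms > 0)
  if (support_ms < 5 / alpha)
    stop("support_ms must be at least 5 / alpha")
  tau <- seq(0, support_ms, by = step_ms)
  w <- alpha^2 * tau * exp(-alpha * tau)
  w <- w / sum(w)
  structure(w, alpha = alpha, step_ms = step_ms, class = "rate_kernel")
}

#' Kernel-smoothed event-rate curve
#'
#' Raw rate(t) = (sum over trials of the raster at t / n_trials) *
#' sampling_rate, in events/s, causally convolved with the unit-sum kernel:
#' an event contributes no rate before its onset, and total event mass is
#' conserved (up to truncation of kernels overhanging the window end).
#'
#' @param raster Matrix from [event_raster()].
#' @param sampling_rate Samples per second (default 500).
#' @param kernel A [smoothing_kernel()]; `NULL` for the unsmoothed rate.
#' @return List of class `rate_curve`: `time_ms`, `rate_hz`, `n_trials`.
#' @export
rate_curve <- function(raster, sampling_rate = 500,
                       kernel = smoothing_kernel(step_ms = 1000 / sampling_rate)) {
  n_trials <- nrow(raster)
  if (is.null(n_trials) || n_trials == 0) stop("raster has no trials")
  raw <- colSums(raster) / n_trials * sampling_rate
  rate <- if (is.null(kernel)) raw else causal_convolve(raw, kernel)
  structure(list(time_ms = attr(raster, "time_ms"), rate_hz = rate,
                 n_trials = n_trials),
            class = "rate_curve")
}

# causal FIR convolution with left zero padding; output has the input length
causal_convolve <- function(x, kernel) {
  k <- as.numeric(kernel)
  xp <- c(rep(0, length(k) - 1), x)
  out <- stats::filter(xp, k, method = "convolution", sides = 1)
  as.numeric(out[length(k):length(xp)])
}

#' Segment means of a rate (or pupil) curve
#'
#' Means over contiguous half-open bins, by default the four 250-ms segments
#' S1 (0--250 ms), S2 (250--500), S3 (500--750), S4 (750--1000) used for
#' between-experiment comparisons.
#'
#' @param curve A `rate_curve`, or any list with `time_ms` and a values
#'   vector named `rate_hz` (or pass `values`).
#' @param boundaries_ms Strictly increasing segment boundaries.
#' @param labels Segment labels (length = number of bins).
#' @param values Optional values vector overriding `curve$rate_hz`.
#' @return Named numeric vector of per-segment means.
#' @export
bin_segments <- function(curve, boundaries_ms = c(0, 250, 500, 750, 1000),
                         labels = paste0("S", seq_len(length(boundaries_ms) - 1)),
                         values = NULL) {
  stopifnot(all(diff(boundaries_ms) > 0),
            length(labels) == length(boundaries_ms) - 1)
  t <- curve$time_ms
  v <- if (is.null(values)) curve$rate_hz else values
  if (min(t) > boundaries_ms[1] ||
      max(t) < boundaries_ms[length(boundaries_ms)] - (t[2] - t[1]))
    stop("curve window does not cover the segment scheme")
  out <- vapply(seq_len(length(boundaries_ms) - 1), function(i) {
    sel <- t >= boundaries_ms[i] & t < boundaries_ms[i + 1]
    mean(v[sel])
  }, numeric(1))
  names(out) <- labels
  out
}
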