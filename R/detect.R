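#' Microsaccade detection parameters
#'
#' Velocity-threshold detection: samples whose horizontal velocity exceeds
#' `lambda` times the median-based standard deviation of the session's
#' horizontal velocities become candidates; candidates shorter than 3 ms or
#' longer than 110 ms are excluded, as is any event whose interval to the
#' previous kept event is shorter than 20 ms.
#'
#' @param lambda Threshold multiplier (default 8).
#' @param min_duration_ms,max_duration_ms Duration filter bounds (3, 110 ms).
#' @param min_interval_ms Minimum interval to the previous kept event
#'   (default 20 ms).
#' @param velocity_window Samples in the moving-window velocity estimator
#'   (currently 5, the only supported width).
#' @param sigma_floor Median-based SDs below this flag the session as
#'   degenerate (default 1e-6 deg/s).
#' @param criterion `"horizontal"` (default): threshold `|v_x|` only;
#'   `"elliptic"`: the 2-D criterion `(v_x/th_x)^2 + (v_y/th_y)^2 > 1`.
#' @param interval_reference `"offset"` (default, stricter): the 20-ms rule
#'   measures previous kept offset to next onset; `"onset"`: onset to onset.
#' @return A validated list of class `detection_params`.
#' @export
detection_params <- function(lambda = 8, min_duration_ms = 3,
                             max_duration_ms = 110, min_interval_ms = 20,
                             velocity_window = 5L, sigma_floor = 1e-6,
                             criterion = c("horizontal", "elliptic"),
                             interval_reference = c("offset", "onset")) {
  criterion <- match.arg(criterion)
  interval_reference <- match.arg(interval_reference)
  stopifnot(lambda > 0, min_duration_ms > 0,
            min_duration_ms < max_duration_ms, min_interval_ms >= 0,
            velocity_window == 5L)
  structure(list(lambda = lambda, min_duration_ms = min_duration_ms,
                 max_duration_ms = max_duration_ms,
                 min_interval_ms = min_interval_ms,
                 velocity_window = as.integer(velocity_window),
                 sigma_floor = sigma_floor, criterion = criterion,
                 interval_reference = interval_reference),
            class = "detection_params")
}

#' Eye velocity by the 5-sample moving-window estimator
#'
#' `v[n] = (x[n+2] + x[n+1] - x[n-1] - x[n-2]) / (6 * dt)`, exact for
#' linear signals and noise-suppressing for fixational data. The first and
#' last two samples are marked invalid (`NA`). Samples adjacent to missing
#' positions (blinks) propagate `NA`.
#'
#' @param recording A `gaze_recording` with at least 5 samples.
#' @return data.frame `time_ms`, `vx_deg_s`, `vy_deg_s`.
#' @export
compute_velocity <- function(recording) {
  stopifnot(inherits(recording, "gaze_recording"))
  s <- recording$samples
  n <- nrow(s)
  if (n < 5) stop("recording shorter than the 5-sample velocity window")
  dt_s <- (1000 / recording$sampling_rate) / 1000
  win_vel <- function(x) {
    v <- rep(NA_real_, n)
    i <- 3:(n - 2)
    v[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt_s)
    v
  }
  data.frame(time_ms = s$time_ms, vx_deg_s = win_vel(s$x_deg),
             vy_deg_s = win_vel(s$y_deg))
}

#' Median-based standard deviation
#'
#' `sigma = sqrt(median(v^2) - median(v)^2)`, clipped at 0; robust to the
#' velocity spikes produced by the saccades themselves. `NA`s are dropped.
#'
#' @param v Velocity samples (one component), deg/s.
#' @return sigma, deg/s.
#' @export
median_sd <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v)) stop("no valid velocity samples")
  sqrt(max(0, stats::median(v^2) - stats::median(v)^2))
}

#' Session velocity statistics and detection threshold
#'
#' @param vx,vy Session-wide velocity components (vertical needed only for
#'   the elliptic criterion), deg/s.
#' @param params A `detection_params` object.
#' @return List of class `velocity_stats`: `sigma_x`, `sigma_y`,
#'   `threshold_x`, `threshold_y` (= lambda * sigma), `degenerate`.
#' @export
velocity_stats <- function(vx, vy = NULL, params = detection_params()) {
  sigma_x <- median_sd(vx)
  sigma_y <- if (!is.null(vy)) median_sd(vy) else NA_real_
  degenerate <- sigma_x < params$sigma_floor ||
    (params$criterion == "elliptic" &&
       (is.na(sigma_y) || sigma_y < params$sigma_floor))
  structure(list(sigma_x = sigma_x, sigma_y = sigma_y,
                 threshold_x = params$lambda * sigma_x,
                 threshold_y = params$lambda * sigma_y,
                 degenerate = degenerate),
            class = "velocity_stats")
}

#' Supra-threshold velocity excursions (candidate events)
#'
#' Maximal runs of consecutive samples exceeding the threshold, lasting at
#' least `min_samples` samples. Onset is the first sample's time; offset is
#' the last sample's time plus one sample period (half-open convention), so
#' duration = n_samples * dt.
#'
#' @param velocity data.frame from [compute_velocity()].
#' @param stats_ A `velocity_stats` object (non-degenerate).
#' @param params A `detection_params` object.
#' @param min_samples Minimum run length; defaults to
#'   `ceiling(min_duration_ms / dt)`. Pass 1 to obtain every excursion (as
#'   used for gaze segmentation).
#' @return data.frame `onset_ms`, `offset_ms`, `duration_ms`, `n_samples`.
#' @export
detect_candidates <- function(velocity, stats_, params = detection_params(),
                              min_samples = NULL) {
  if (stats_$degenerate)
    stop("degenerate velocity statistics: session unusable for detection")
  dt <- velocity$time_ms[2] - velocity$time_ms[1]
  if (is.null(min_samples))
    min_samples <- ceiling(params$min_duration_ms / dt)
  above <- if (params$criterion == "horizontal") {
    abs(velocity$vx_deg_s) > stats_$threshold_x
  } else {
    (velocity$vx_deg_s / stats_$threshold_x)^2 +
      (velocity$vy_deg_s / stats_$threshold_y)^2 > 1
  }
  above[is.na(above)] <- FALSE
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_samples)
  data.frame(onset_ms = velocity$time_ms[starts[keep]],
             offset_ms = velocity$time_ms[ends[keep]] + dt,
             duration_ms = r$lengths[keep] * dt,
             n_samples = r$lengths[keep])
}

#' Apply the duration and inter-event interval filters
#'
#' Single left-to-right pass: drop candidates with duration outside
#' `[min_duration_ms, max_duration_ms]`, then drop any event closer than
#' `min_interval_ms` to the previous *kept* event (keep-earlier
#' tie-breaking). Output inter-event intervals are therefore all >=
#' `min_interval_ms`, and the operation is idempotent.
#'
#' @param candidates data.frame from [detect_candidates()], sorted by onset.
#' @param params A `detection_params` object.
#' @return The surviving subset of `candidates`.
#' @export
filter_events <- function(candidates, params = detection_params()) {
  if (!nrow(candidates)) return(candidates)
  if (is.unsorted(candidates$onset_ms))
    stop("candidates must be sorted by onset")
  ok <- candidates$duration_ms >= params$min_duration_ms &
    candidates$duration_ms <= params$max_duration_ms
  candidates <- candidates[ok, , drop = FALSE]
  if (nrow(candidates) <= 1) return(candidates)
  keep <- logical(nrow(candidates))
  keep[1] <- TRUE
  last_ref <- if (params$interval_reference == "offset")
    candidates$offset_ms[1] else candidates$onset_ms[1]
  for (i in 2:nrow(candidates)) {
    if (candidates$onset_ms[i] - last_ref >= params$min_interval_ms) {
      keep[i] <- TRUE
      last_ref <- if (params$interval_reference == "offset")
        candidates$offset_ms[i] else candidates$onset_ms[i]
    }
  }
  candidates[keep, , drop = FALSE]
}

#' Amplitude and peak velocity of detected events
#'
#' Amplitude is the Euclidean distance between the mean eye position of the
#' 2 samples preceding the onset and the 2 samples following the offset;
#' peak velocity is the maximum 2-D velocity magnitude within the event.
#' Events at the trace edge are computed from the available samples and
#' flagged.
#'
#' @param recording The `gaze_recording` the events came from.
#' @param velocity Its [compute_velocity()] output.
#' @param events data.frame with `onset_ms`, `offset_ms`.
#' @return `events` with `amplitude_deg`, `peak_velocity_deg_s`, `edge`
#'   columns added.
#' @export
event_properties <- function(recording, velocity, events) {
  s <- recording$samples
  n <- nrow(s)
  dt <- 1000 / recording$sampling_rate
  amp <- pv <- rep(NA_real_, nrow(events))
  edge <- logical(nrow(events))
  for (k in seq_len(nrow(events))) {
    i0 <- which.min(abs(s$time_ms - events$onset_ms[k]))
    i1 <- which.min(abs(s$time_ms - (events$offset_ms[k] - dt))) # last sample
    pre <- (i0 - 2):(i0 - 1)
    post <- (i1 + 1):(i1 + 2)
    edge[k] <- any(pre < 1) || any(post > n)
    pre <- pre[pre >= 1]
    post <- post[post <= n]
    if (!length(pre)) pre <- i0
    if (!length(post)) post <- i1
    dx <- mean(s$x_deg[post], na.rm = TRUE) - mean(s$x_deg[pre], na.rm = TRUE)
    dy <- mean(s$y_deg[post], na.rm = TRUE) - mean(s$y_deg[pre], na.rm = TRUE)
    amp[k] <- sqrt(dx^2 + dy^2)
    vmag <- sqrt(velocity$vx_deg_s[i0:i1]^2 + velocity$vy_deg_s[i0:i1]^2)
    pv[k] <- if (all(is.na(vmag))) NA_real_ else max(vmag, na.rm = TRUE)
  }
  events$amplitude_deg <- amp
  events$peak_velocity_deg_s <- pv
  events$edge <- edge
  events
}

#' Detect microsaccades across a session
#'
#' Runs the full detection pipeline: per-trial 5-sample-window velocities,
#' one median-based threshold from all the session's horizontal velocities
#' pooled ("within each session"), candidate extraction, duration/interval
#' filters and event properties.
#'
#' @param recordings A list of `gaze_recording`s (one session's trials), or
#'   a single recording.
#' @param params A `detection_params` object.
#' @return List with `events` (data.frame: `session_id`, `trial_id`,
#'   `onset_ms`, `offset_ms`, `duration_ms`, `amplitude_deg`,
#'   `peak_velocity_deg_s`, `edge`), `stats` (the session
#'   `velocity_stats`) and `candidates` (pre-filter, with minimum run
#'   length 1, for gaze segmentation).
#' @export
detect_microsaccades <- function(recordings, params = detection_params()) {
  if (inherits(recordings, "gaze_recording")) recordings <- list(recordings)
  vels <- lapply(recordings, compute_velocity)
  stats_ <- velocity_stats(unlist(lapply(vels, `[[`, "vx_deg_s")),
                           unlist(lapply(vels, `[[`, "vy_deg_s")), params)
  ev_list <- vector("list", length(recordings))
  cand_list <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    cand_all <- detect_candidates(vels[[i]], stats_, params, min_samples = 1L)
    cand <- cand_all[cand_all$n_samples >=
                       ceiling(params$min_duration_ms *
                                 recordings[[i]]$sampling_rate / 1000), ,
                     drop = FALSE]
    ev <- filter_events(cand, params)
    ev <- event_properties(rec, vels[[i]], ev)
    if (nrow(ev)) {
      ev$session_id <- rec$session_id
      ev$trial_id <- rec$trial_id
    }
    ev_list[[i]] <- ev
    if (nrow(cand_all)) {
      cand_all$trial_id <- rec$trial_id
    }
    cand_list[[i]] <- cand_all
  }
  events <- do.call(rbind, ev_list)
  list(events = events, stats = stats_,
       candidates = do.call(rbind, cand_list))
}

#' Main-sequence correlation
#'
#' Pearson correlation between microsaccade amplitude and peak velocity --
#' the near-linear "main sequence" that validates detected events as genuine
#' saccadic eye movements.
#'
#' @param events data.frame with `amplitude_deg` and `peak_velocity_deg_s`.
#' @return List: `r`, `n`, `p_value`.
#' @export
main_sequence <- function(events) {
  ok <- is.finite(events$amplitude_deg) & is.finite(events$peak_velocity_deg_s)
  a <- events$amplitude_deg[ok]
  v <- events$peak_velocity_deg_s[ok]
  if (length(a) < 3) stop("need at least 3 events")
  if (stats::sd(a) == 0 || stats::sd(v) == 0)
    stop("zero variance in amplitude or peak velocity")
  ct <- stats::cor.test(a, v, method = "pearson")
  list(r = unname(ct$estimate), n = length(a), p_value = ct$p.value)
}
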