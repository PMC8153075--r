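#' Simulate behavioral responses for a design
#'
#' For E1--E3, each trial's group-motion report is a Bernoulli draw with
#' p = logistic((SOA - PSE_cond) / s_cond), s_cond = JND_cond / ln 3.
#' For E4, the reaction time is drawn from a normal distribution truncated
#' below at `params$rt$min`, with a condition-specific mean.
#'
#' @param design A `ternus_design`.
#' @param params A `generator_params` object (use [subject_params()] upstream
#'   for subject-level variation; this function uses the values as given).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return The design's trial table with a `group_motion` (logical) column
#'   for E1--E3 or an `rt_ms` column for E4.
#' @export
sample_behavior <- function(design, params, seed = NULL) {
  stopifnot(inherits(design, "ternus_design"))
  validate_generator_params(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- design$trials
  out <- tr[, c("trial_id", "block", "soa_ms", "sound", "direction")]
  if (design$experiment_id == "E4") {
    mu <- ifelse(tr$sound, params$rt$mean_sound, params$rt$mean_baseline)
    out$rt_ms <- rtruncnorm(nrow(tr), mu, params$rt$sd, params$rt$min)
  } else {
    pse <- ifelse(tr$sound, params$pse_sound, params$pse_baseline)
    s <- ifelse(tr$sound, params$jnd_sound, params$jnd_baseline) / log(3)
    p <- stats::plogis((tr$soa_ms - pse) / s)
    out$group_motion <- stats::rbinom(nrow(tr), 1L, p) == 1L
  }
  out
}

# normal truncated below at `lower`, by rejection (acceptance is high for the
# RT defaults: lower bound ~4.5 SD below the mean)
rtruncnorm <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Stimulus-locked microsaccade-rate modulation
#'
#' Multiplicative rate gain at times `t_ms` for one trial: for each Ternus
#' frame onset a piecewise-smooth well (cosine ramps) drops the rate by
#' `depth` after `latency`, holds for `duration`, and recovers into a
#' transient rebound overshoot. The two frames' gains multiply.
#'
#' @param t_ms Times at which to evaluate, ms (absolute trial time).
#' @param trial One row of a design's trial table.
#' @param params A `generator_params` object.
#' @return Numeric gain vector, >= 0, 1 where unmodulated.
#' @export
ms_rate_gain <- function(t_ms, trial, params) {
  cond <- if (trial$sound) "sound" else "baseline"
  m <- params$ms_inhibition[[cond]]
  g <- rep(1, length(t_ms))
  for (t0 in c(trial$frame1_ms, trial$frame2_ms)) {
    tau <- t_ms - t0
    w <- smooth_window(tau, m$latency, m$duration, 50, 100)
    wr <- smooth_window(tau, m$latency + m$duration + 100, m$rebound_duration,
                        100, m$rebound_duration / 2)
    g <- g * pmax(0, 1 - m$depth * w + m$rebound * wr)
  }
  g
}

# cosine-ramped window: 0 before `a`, ramps to 1 over r_up, holds until
# a + width, ramps back to 0 over r_down
smooth_window <- function(tau, a, width, r_up, r_down) {
  out <- numeric(length(tau))
  out[tau >= a + r_up & tau <= a + width] <- 1
  i <- tau > a & tau < a + r_up
  out[i] <- 0.5 * (1 - cos(pi * (tau[i] - a) / r_up))
  j <- tau > a + width & tau < a + width + r_down
  out[j] <- 0.5 * (1 + cos(pi * (tau[j] - a - width) / r_down))
  out
}

# Draw event onsets for an inhomogeneous point process with a refractory
# dead time. `rate_hz` is the target rate on the sample grid `t_ms`
# (step dt_ms). A renewal construction with hazard
# h = rate / (1 - rate * dead_s) compensates the enforced dead time
# (mean event duration + min gap) so realized rates match the nominal rate.
# Returns a data.frame of onset_ms, amplitude_deg, peak_velocity_deg_s,
# duration_ms, theta (direction, radians).
sim_event_times <- function(t_ms, rate_hz, params, x_offset_scale = 0.3) {
  dt_s <- (t_ms[2] - t_ms[1]) / 1000
  mean_dur_s <- 1.875 / params$main_seq_slope *
    exp(params$main_seq_sdlog^2 / 2) # E[D] of the main-sequence draw, s
  dead_s <- mean_dur_s + params$ms_min_gap_ms / 1000
  hz <- rate_hz / pmax(1e-9, 1 - pmin(0.9, rate_hz * dead_s))
  cand <- which(stats::runif(length(t_ms)) < hz * dt_s)
  if (!length(cand))
    return(data.frame(onset_ms = numeric(0), amplitude_deg = numeric(0),
                      peak_velocity_deg_s = numeric(0),
                      duration_ms = numeric(0), theta = numeric(0)))
  dt_ms <- dt_s * 1000
  onset <- amp <- vpk <- dur <- theta <- numeric(0)
  x_off <- 0 # running horizontal offset, used to keep the walk bounded
  blocked_until <- -Inf
  for (i in cand) {
    t0 <- t_ms[i]
    if (t0 < blocked_until) next
    a <- stats::rlnorm(1, params$ms_amp_meanlog, params$ms_amp_sdlog)
    v <- params$main_seq_slope * a *
      stats::rlnorm(1, 0, params$main_seq_sdlog)
    d <- 1875 * a / v # min-jerk: D = 1.875 * A / Vpeak, ms
    d <- min(80, max(6, round(d / dt_ms) * dt_ms))
    v <- 1875 * a / d # actual peak velocity on the rounded duration
    # direction mostly horizontal, drawn to pull the offset back to center
    leftward <- stats::runif(1) < stats::plogis(x_off / x_offset_scale)
    th <- stats::rnorm(1, if (leftward) pi else 0, 15 * pi / 180)
    onset <- c(onset, t0); amp <- c(amp, a); vpk <- c(vpk, v)
    dur <- c(dur, d); theta <- c(theta, th)
    x_off <- x_off + a * cos(th)
    blocked_until <- t0 + d + params$ms_min_gap_ms
  }
  data.frame(onset_ms = onset, amplitude_deg = amp,
             peak_velocity_deg_s = vpk, duration_ms = dur, theta = theta)
}

# minimum-jerk displacement profile on u in [0, 1]
minjerk <- function(u) {
  u <- pmin(1, pmax(0, u))
  u^3 * (10 - 15 * u + 6 * u^2)
}

#' Simulate one trial's gaze trace
#'
#' Generates a 500-Hz eye-position trace: bounded AR(1) fixational drift plus
#' microsaccade waveforms (smooth minimum-jerk displacement ramps) placed by
#' an inhomogeneous point process whose rate is `ms_base_rate` modulated by
#' the stimulus-locked inhibition/rebound gain of [ms_rate_gain()]; a 20-ms
#' minimum gap between events is enforced. Blinks (gaze and pupil set to
#' missing) are inserted as a Poisson process. The injected ground-truth
#' events are attached as `attr(, "truth")`.
#'
#' @param trial One row of a design's trial table.
#' @param params A `generator_params` object.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param window_ms Simulation window relative to the first frame onset;
#'   must cover at least \[-500, +1500\] ms.
#' @param sampling_rate Samples per second (default 500).
#' @param session_id,trial_id Identifiers stored on the recording.
#' @return A [gaze_recording()] (pupil channel all-missing until
#'   [simulate_pupil_trial()] fills it).
#' @export
simulate_gaze_trial <- function(trial, params, seed = NULL,
                                window_ms = c(-800, 1600),
                                sampling_rate = 500,
                                session_id = "sim", trial_id = trial$trial_id) {
  validate_generator_params(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (window_ms[1] > -500 || window_ms[2] < 1500)
    stop("window_ms must cover at least [-500, +1500] ms around frame1")
  dt <- 1000 / sampling_rate
  if (diff(window_ms) %% dt != 0)
    stop("window length must be divisible by the sample period")
  t_ms <- seq(trial$frame1_ms + window_ms[1],
              trial$frame1_ms + window_ms[2] - dt, by = dt)
  n <- length(t_ms)

  # fixational drift: AR(1) per axis
  x <- as.numeric(stats::filter(stats::rnorm(n, 0, params$drift_sd),
                                params$drift_ar, method = "recursive"))
  y <- as.numeric(stats::filter(stats::rnorm(n, 0, params$drift_sd),
                                params$drift_ar, method = "recursive"))

  rate <- params$ms_base_rate * ms_rate_gain(t_ms, trial, params)
  if (any(rate < 0)) stop("negative microsaccade rate")
  ev <- sim_event_times(t_ms, rate, params)
  for (k in seq_len(nrow(ev))) {
    i0 <- match(ev$onset_ms[k], t_ms)
    prof <- ev$amplitude_deg[k] *
      minjerk((t_ms[i0:n] - ev$onset_ms[k]) / ev$duration_ms[k])
    x[i0:n] <- x[i0:n] + prof * cos(ev$theta[k])
    y[i0:n] <- y[i0:n] + prof * sin(ev$theta[k])
  }

  # blinks: Poisson count over the window, gaze lost while the lid is down
  blink <- rep(FALSE, n)
  n_blink <- stats::rpois(1, params$pupil$blink_rate * diff(window_ms) / 1000)
  if (n_blink > 0) {
    starts <- sort(stats::runif(n_blink, t_ms[1], t_ms[n]))
    durs <- pmax(60, stats::rnorm(n_blink, params$pupil$blink_dur_mean,
                                  params$pupil$blink_dur_sd))
    for (b in seq_len(n_blink))
      blink[t_ms >= starts[b] & t_ms < starts[b] + durs[b]] <- TRUE
  }
  x[blink] <- NA_real_
  y[blink] <- NA_real_

  rec <- gaze_recording(time_ms = t_ms, x_deg = x, y_deg = y,
                        pupil = rep(NA_real_, n),
                        sampling_rate = sampling_rate,
                        session_id = session_id, trial_id = trial_id)
  attr(rec, "truth") <- ev
  attr(rec, "blink") <- blink
  rec
}

#' Pupil impulse response
#'
#' Gamma-shaped kernel `h(t) = (t/tmax)^n * exp(n * (1 - t/tmax))` for
#' `t >= 0`, normalized to peak 1 at `t = tmax`.
#'
#' @param t_ms Times since the driving event, ms.
#' @param n Shape exponent.
#' @param tmax_ms Time to peak, ms.
#' @return Response values (0 for `t_ms < 0`).
#' @export
pupil_irf <- function(t_ms, n = 10.1, tmax_ms = 930) {
  h <- numeric(length(t_ms))
  i <- t_ms > 0
  h[i] <- (t_ms[i] / tmax_ms)^n * exp(n * (1 - t_ms[i] / tmax_ms))
  h
}

#' Add the pupil channel to a simulated gaze recording
#'
#' Pupil trace = session baseline level (+ per-trial wander) + a gamma-shaped
#' impulse response per stimulus event (each displayed frame contributes
#' `visual_gain`; each beep adds `sound_gain` on sound trials) + AR(1)
#' measurement noise. Samples inside the trial's blink intervals are set to
#' missing.
#'
#' @param recording A recording from [simulate_gaze_trial()].
#' @param trial The corresponding trial row.
#' @param params A `generator_params` object.
#' @param seed Optional integer seed.
#' @return The recording with its pupil channel filled in.
#' @export
simulate_pupil_trial <- function(recording, trial, params, seed = NULL) {
  validate_generator_params(params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pp <- params$pupil
  t_ms <- recording$samples$time_ms
  p <- rep(pp$base_level + stats::rnorm(1, 0, pp$level_sd), length(t_ms))
  events <- c(if (trial$has_frames) c(trial$frame1_ms, trial$frame2_ms),
              if (trial$sound) c(trial$beep1_ms, trial$beep2_ms))
  gains <- c(if (trial$has_frames) rep(pp$visual_gain, 2),
             if (trial$sound) rep(pp$sound_gain, 2))
  for (k in seq_along(events))
    p <- p + gains[k] * pupil_irf(t_ms - events[k], pp$irf_n, pp$irf_tmax)
  if (pp$noise_sd > 0)
    p <- p + as.numeric(stats::filter(
      stats::rnorm(length(t_ms), 0, pp$noise_sd * sqrt(1 - pp$noise_ar^2)),
      pp$noise_ar, method = "recursive"))
  blink <- attr(recording, "blink")
  if (!is.null(blink)) p[blink] <- NA_real_
  recording$samples$pupil <- p
  recording
}

#' Simulate a full session (one virtual participant)
#'
#' Draws subject-level parameters, then simulates behavior and the gaze and
#' pupil channels for every trial of the design. The whole session is a pure
#' function of `(design, params, seed)`.
#'
#' @param design A `ternus_design`.
#' @param params A `generator_params` object (population-level; subject-level
#'   values are drawn inside).
#' @param session_id Identifier for the session.
#' @param seed Integer seed.
#' @return A list of class `ternus_session`: `recordings` (one per trial),
#'   `behavior`, `truth_events`, `design`, `session_id`,
#'   `subject_effect`, `subject_params`.
#' @export
simulate_session <- function(design, params = generator_params(),
                             session_id = "sub-01", seed = 1L) {
  stopifnot(inherits(design, "ternus_design"))
  set.seed(as.integer(seed))
  sp <- subject_params(params)
  behavior <- sample_behavior(design, sp)
  tr <- design$trials
  recordings <- vector("list", nrow(tr))
  truth <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    rec <- simulate_gaze_trial(tr[i, ], sp, session_id = session_id,
                               trial_id = tr$trial_id[i])
    rec <- simulate_pupil_trial(rec, tr[i, ], sp)
    recordings[[i]] <- rec
    tv <- attr(rec, "truth")
    if (nrow(tv)) tv$trial_id <- tr$trial_id[i]
    truth[[i]] <- tv
  }
  structure(list(recordings = recordings, behavior = behavior,
                 truth_events = do.call(rbind, truth), design = design,
                 session_id = session_id, seed = as.integer(seed),
                 subject_effect = sp$subject_effect, subject_params = sp),
            class = "ternus_session")
}

#' Write a synthetic multi-subject dataset to disk
#'
#' Simulates `n_subjects` sessions of `experiment_id` and writes, per
#' subject, one sample file per trial (gaze_io dialect), an event table and a
#' response table, plus a JSON manifest recording seeds and the parameter
#' snapshot so the dataset can be regenerated byte-identically.
#'
#' @param out_dir Output directory (created if needed).
#' @param experiment_id Which design to simulate.
#' @param n_subjects Number of virtual participants (>= 1).
#' @param params A `generator_params` object.
#' @param seed Base seed; subject s uses design seed `seed*1000 + s` and
#'   session seed `seed*1000 + 500 + s`.
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(out_dir, experiment_id = "E1", n_subjects = 2L,
                             params = generator_params(), seed = 1L) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(experiment_id = experiment_id, n_subjects = n_subjects,
                   seed = as.integer(seed), params = unclass(params),
                   subjects = list())
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("sub-%02d", s)
    sdir <- file.path(out_dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    design_seed <- as.integer(seed) * 1000L + s
    session_seed <- as.integer(seed) * 1000L + 500L + s
    design <- build_design(experiment_id, seed = design_seed)
    ses <- simulate_session(design, params, session_id = sid,
                            seed = session_seed)
    for (rec in ses$recordings)
      write_samples(rec, file.path(sdir, sprintf("trial-%04d.tsv",
                                                 rec$trial_id)))
    utils::write.csv(design$trials, file.path(sdir, "events.csv"),
                     row.names = FALSE)
    utils::write.csv(ses$behavior, file.path(sdir, "responses.csv"),
                     row.names = FALSE)
    manifest$subjects[[sid]] <- list(design_seed = design_seed,
                                     session_seed = session_seed,
                                     n_trials = nrow(design$trials))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [generate_dataset()].
#' @param out_dir Where to write the regenerated dataset.
#' @return The manifest, invisibly.
#' @export
regenerate_dataset <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  pars <- do.call(generator_params, m$params[setdiff(names(m$params), NULL)])
  generate_dataset(out_dir, experiment_id = m$experiment_id,
                   n_subjects = m$n_subjects, params = pars, seed = m$seed)
}
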