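#' Parameters of the synthetic-data generator
#'
#' Bundles every tunable of the behavioral, oculomotor and pupillometric
#' generators. Defaults emulate the pooled Ternus experiments: the
#' psychometric defaults are the pooled condition means (PSE 180.1 ms
#' baseline / 100.2 ms sound; JND 37.9 / 42.6 ms), and the oculomotor
#' defaults produce a stimulus-locked microsaccadic inhibition that is
#' deepened and prolonged by sound, so the rate difference in the late
#' (750--1000 ms) window is negative (sound below baseline).
#'
#' @param pse_baseline,pse_sound Generating points of subjective equality, ms.
#' @param jnd_baseline,jnd_sound Generating just-noticeable differences, ms
#'   (logistic scale s = JND / ln 3).
#' @param ms_base_rate Unmodulated microsaccade rate, events/s.
#' @param ms_inhibition Per-condition rate modulation locked to each Ternus
#'   frame: lists with `depth` (fractional rate drop, 0--1), `latency` (ms from
#'   frame onset), `duration` (ms at full depth before recovery), `rebound`
#'   (fractional overshoot after recovery) and `rebound_duration` (ms).
#' @param ms_amp_meanlog,ms_amp_sdlog Lognormal amplitude distribution
#'   (degrees).
#' @param main_seq_slope Main-sequence slope, peak velocity per degree of
#'   amplitude (1/s).
#' @param main_seq_sdlog Multiplicative lognormal noise (sdlog) on peak
#'   velocity around the main sequence.
#' @param ms_min_gap_ms Minimum gap between a generated event's offset and the
#'   next event's onset, ms.
#' @param drift_sd,drift_ar Fixational drift model: AR(1) per-sample
#'   innovation SD (degrees) and autoregressive coefficient, per axis.
#' @param pupil Pupil model: `base_level` (arbitrary units), impulse-response
#'   shape `irf_n` and time-to-peak `irf_tmax` (ms), `visual_gain` and
#'   `sound_gain` (a.u. added per frame / per beep), `level_sd` (trial-to-trial
#'   baseline wander, a.u.), `noise_sd` and `noise_ar` (AR(1) measurement
#'   noise), `blink_rate` (1/s), `blink_dur_mean`, `blink_dur_sd` (ms).
#' @param rt Control-experiment reaction times: means per condition, common
#'   SD, truncation lower bound (ms).
#' @param subject_effect_sd SD of the per-subject effect-strength scalar
#'   (mean 1, truncated at 0) that jointly scales the sound-induced PSE shift
#'   and the sound-induced extra oculomotor inhibition.
#' @param pse_subject_sd,jnd_subject_sd Independent per-subject jitter (ms) on
#'   baseline PSE and on JNDs.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(
    pse_baseline = 180.1, pse_sound = 100.2,
    jnd_baseline = 37.9, jnd_sound = 42.6,
    ms_base_rate = 1.5,
    ms_inhibition = list(
      baseline = list(depth = 0.70, latency = 100, duration = 350,
                      rebound = 0.40, rebound_duration = 300),
      sound    = list(depth = 0.90, latency = 100, duration = 600,
                      rebound = 0.40, rebound_duration = 300)),
    ms_amp_meanlog = log(0.5), ms_amp_sdlog = 0.35,
    main_seq_slope = 100, main_seq_sdlog = 0.12,
    ms_min_gap_ms = 20,
    drift_sd = 0.003, drift_ar = 0.99,
    pupil = list(base_level = 3000, irf_n = 10.1, irf_tmax = 930,
                 visual_gain = 60, sound_gain = 40, level_sd = 30,
                 noise_sd = 8, noise_ar = 0.95,
                 blink_rate = 0.05, blink_dur_mean = 150, blink_dur_sd = 30),
    rt = list(mean_baseline = 603, mean_sound = 537, sd = 100, min = 150),
    subject_effect_sd = 0.3,
    pse_subject_sd = 12, jnd_subject_sd = 4) {
  p <- list(pse_baseline = pse_baseline, pse_sound = pse_sound,
            jnd_baseline = jnd_baseline, jnd_sound = jnd_sound,
            ms_base_rate = ms_base_rate, ms_inhibition = ms_inhibition,
            ms_amp_meanlog = ms_amp_meanlog, ms_amp_sdlog = ms_amp_sdlog,
            main_seq_slope = main_seq_slope, main_seq_sdlog = main_seq_sdlog,
            ms_min_gap_ms = ms_min_gap_ms,
            drift_sd = drift_sd, drift_ar = drift_ar,
            pupil = pupil, rt = rt,
            subject_effect_sd = subject_effect_sd,
            pse_subject_sd = pse_subject_sd, jnd_subject_sd = jnd_subject_sd)
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  if (p$jnd_baseline <= 0 || p$jnd_sound <= 0) stop("jnd must be > 0")
  if (p$ms_base_rate < 0) stop("ms_base_rate must be >= 0")
  for (cond in c("baseline", "sound")) {
    m <- p$ms_inhibition[[cond]]
    if (is.null(m)) stop("ms_inhibition needs 'baseline' and 'sound' entries")
    if (m$depth < 0 || m$depth > 1) stop("inhibition depth must lie in [0, 1]")
    if (m$latency < 0 || m$duration < 0 || m$rebound < 0 ||
        m$rebound_duration < 0)
      stop("inhibition timing parameters must be >= 0")
  }
  if (p$ms_min_gap_ms < 0) stop("ms_min_gap_ms must be >= 0")
  if (p$drift_sd < 0) stop("drift_sd must be >= 0")
  if (p$pupil$noise_sd < 0) stop("pupil noise_sd must be >= 0")
  if (p$pupil$blink_rate < 0) stop("blink_rate must be >= 0")
  if (p$rt$sd <= 0) stop("rt sd must be > 0")
  invisible(TRUE)
}

#' Per-subject realization of the generator parameters
#'
#' Draws the subject effect-strength scalar and subject-level psychometric
#' parameters from the current RNG stream. Stronger subjects (effect > 1)
#' receive both a larger sound-induced PSE shift and deeper/longer
#' sound-induced inhibition, which induces the negative coupling between
#' sound-induced oculomotor inhibition and the group-motion report shift.
#'
#' @param params A `generator_params` object.
#' @return `params` with subject-level psychometric values and sound
#'   inhibition substituted, plus a `subject_effect` element.
#' @keywords internal
subject_params <- function(params) {
  eff <- max(0, stats::rnorm(1, 1, params$subject_effect_sd))
  p <- params
  p$subject_effect <- eff
  shift <- (params$pse_baseline - params$pse_sound) * eff
  p$pse_baseline <- params$pse_baseline +
    stats::rnorm(1, 0, params$pse_subject_sd)
  p$pse_sound <- p$pse_baseline - shift
  p$jnd_baseline <- max(5, params$jnd_baseline +
                          stats::rnorm(1, 0, params$jnd_subject_sd))
  p$jnd_sound <- max(5, params$jnd_sound +
                       stats::rnorm(1, 0, params$jnd_subject_sd))
  b <- params$ms_inhibition$baseline
  s <- params$ms_inhibition$sound
  p$ms_inhibition$sound <- list(
    depth = min(1, max(0, b$depth + (s$depth - b$depth) * eff)),
    latency = s$latency,
    duration = max(0, b$duration + (s$duration - b$duration) * eff),
    rebound = s$rebound,
    rebound_duration = s$rebound_duration)
  p
}
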