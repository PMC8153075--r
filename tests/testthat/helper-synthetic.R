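# Small fixtures built in code, shared across test files.

# a minimal design object with hand-chosen trials (one row per trial)
mini_design <- function(soa_ms, sound, experiment_id = "E1",
                        frame1_ms = 1000) {
  n <- max(length(soa_ms), length(sound))
  soa_ms <- rep_len(soa_ms, n)
  sound <- rep_len(sound, n)
  trials <- data.frame(
    trial_id = seq_len(n), block = 1L, soa_ms = soa_ms,
    isi_ms = soa_ms - 30, sound = sound,
    direction = rep_len(c("left", "right"), n),
    has_frames = experiment_id != "E4",
    fix_dur_ms = 4000, frame1_ms = frame1_ms,
    frame2_ms = frame1_ms + soa_ms,
    probe_ms = frame1_ms + soa_ms + 330,
    stringsAsFactors = FALSE)
  trials$beep1_ms <- ifelse(trials$sound, trials$frame1_ms, NA_real_)
  trials$beep2_ms <- ifelse(trials$sound, trials$frame2_ms, NA_real_)
  structure(list(experiment_id = experiment_id, trials = trials,
                 blocks = data.frame(block = 1L, label = "test"),
                 seed = 0L),
            class = "ternus_design")
}

# a recording with given position channels on a 500-Hz grid
make_recording <- function(x, y = rep(0, length(x)),
                           pupil = rep(NA_real_, length(x)),
                           t0 = 0, sampling_rate = 500, trial_id = 1L) {
  n <- length(x)
  gaze_recording(time_ms = seq(t0, by = 1000 / sampling_rate,
                               length.out = n),
                 x_deg = x, y_deg = y, pupil = pupil,
                 sampling_rate = sampling_rate,
                 session_id = "test", trial_id = trial_id)
}

# velocity-stats stub for candidate-detection tests
fake_stats <- function(threshold, threshold_y = threshold) {
  structure(list(sigma_x = threshold / 8, sigma_y = threshold_y / 8,
                 threshold_x = threshold, threshold_y = threshold_y,
                 degenerate = FALSE),
            class = "velocity_stats")
}

# independent brute-force threshold-crossing detector: explicit sample loop,
# no rle; onset/offset/duration per the half-open convention
oracle_candidates <- function(time_ms, vx, threshold, min_samples) {
  dt <- time_ms[2] - time_ms[1]
  above <- !is.na(vx) & abs(vx) > threshold
  onsets <- offsets <- numeric(0)
  i <- 1
  n <- length(vx)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_samples) {
        onsets <- c(onsets, time_ms[i])
        offsets <- c(offsets, time_ms[j] + dt)
      }
      i <- j + 1
    } else i <- i + 1
  }
  data.frame(onset_ms = onsets, offset_ms = offsets)
}
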