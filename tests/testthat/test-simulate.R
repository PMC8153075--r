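p_defaults <- generator_params()

test_that("group-motion probability is 0.5 at the generating PSE", {
  d <- mini_design(soa_ms = 170, sound = FALSE)
  d$trials <- d$trials[rep(1, 10000), ]
  d$trials$trial_id <- seq_len(10000)
  pp <- generator_params(pse_baseline = 170, pse_sound = 120)
  beh <- sample_behavior(d, pp, seed = 1)
  expect_equal(mean(beh$group_motion), 0.5, tolerance = 0.02)
})

test_that("group-motion proportion approaches 1 far above the PSE", {
  d <- mini_design(soa_ms = 260, sound = FALSE)
  d$trials <- d$trials[rep(1, 2000), ]
  d$trials$trial_id <- seq_len(2000)
  pp <- generator_params(pse_baseline = 100, jnd_baseline = 10)
  beh <- sample_behavior(d, pp, seed = 2)
  expect_gt(mean(beh$group_motion), 0.99)
})

test_that("behavioral generator and psychometric fitter form a recovery loop", {
  n_per <- 2000
  d <- mini_design(soa_ms = rep(soa_levels(), each = n_per), sound = FALSE)
  beh <- sample_behavior(d, p_defaults, seed = 3)
  agg <- aggregate(group_motion ~ soa_ms, beh,
                   function(g) c(k = sum(g), n = length(g)))
  fit <- fit_psychometric(agg$soa_ms, agg$group_motion[, "k"],
                          agg$group_motion[, "n"])
  # SE of the PSE at n = 14,000 trials is well under 1 ms
  expect_equal(pse(fit), p_defaults$pse_baseline, tolerance = 2 / 180)
  expect_equal(jnd(fit), p_defaults$jnd_baseline, tolerance = 2 / 38)
})

test_that("E4 reaction times are truncated normals with condition means", {
  d <- build_design("E4", seed = 4)
  beh <- sample_behavior(d, p_defaults, seed = 4)
  expect_true(all(beh$rt_ms >= p_defaults$rt$min))
  expect_equal(mean(beh$rt_ms[beh$sound]), p_defaults$rt$mean_sound,
               tolerance = 0.05)
  expect_equal(mean(beh$rt_ms[!beh$sound]), p_defaults$rt$mean_baseline,
               tolerance = 0.05)
  expect_error(sample_behavior(d, generator_params(jnd_sound = -1), seed = 1))
})

test_that("homogeneous point process realizes the nominal event rate", {
  ph <- generator_params(ms_inhibition = list(
    baseline = list(depth = 0, latency = 0, duration = 0, rebound = 0,
                    rebound_duration = 0),
    sound = list(depth = 0, latency = 0, duration = 0, rebound = 0,
                 rebound_duration = 0)))
  set.seed(5)
  t_ms <- seq(0, 998, by = 2)
  counts <- replicate(10000,
                      nrow(ternuseye:::sim_event_times(t_ms, rep(1.5, 500), ph)))
  expect_equal(mean(counts), 1.5, tolerance = 0.05 / 1.5)
})

test_that("generated events respect the minimum inter-event gap", {
  set.seed(6)
  t_ms <- seq(0, 4998, by = 2)
  ev <- ternuseye:::sim_event_times(t_ms, rep(5, length(t_ms)), p_defaults)
  if (nrow(ev) > 1) {
    gaps <- ev$onset_ms[-1] - (ev$onset_ms[-nrow(ev)] +
                                 ev$duration_ms[-nrow(ev)])
    expect_true(all(gaps >= p_defaults$ms_min_gap_ms))
  }
})

test_that("detector recovers injected microsaccades with sample-level onsets", {
  d <- build_design("E1", seed = 11)
  n_tr <- 2000
  idx <- rep_len(seq_len(nrow(d$trials)), n_tr)
  set.seed(11)
  recs <- vector("list", n_tr)
  truths <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    r <- simulate_gaze_trial(d$trials[idx[i], ], p_defaults, trial_id = i)
    recs[[i]] <- r
    tv <- attr(r, "truth")
    if (nrow(tv)) tv$trial_id <- i
    truths[[i]] <- tv
  }
  truth <- do.call(rbind, truths)
  det <- detect_microsaccades(recs)
  err <- vapply(seq_len(nrow(truth)), function(k) {
    ev <- det$events[det$events$trial_id == truth$trial_id[k], ]
    if (!nrow(ev)) return(Inf)
    min(abs(ev$onset_ms - truth$onset_ms[k]))
  }, numeric(1))
  expect_gte(mean(err <= 2), 0.90) # within one 2-ms sample
  # injected events lie on a credible main sequence
  expect_gte(cor(truth$amplitude_deg, truth$peak_velocity_deg_s), 0.7)
  # and the detected events reproduce it
  expect_gte(main_sequence(det$events)$r, 0.7)
})

test_that("gaze simulation is seed-deterministic and window-checked", {
  tr <- mini_design(170, TRUE)$trials[1, ]
  r1 <- simulate_gaze_trial(tr, p_defaults, seed = 9)
  r2 <- simulate_gaze_trial(tr, p_defaults, seed = 9)
  expect_identical(r1$samples, r2$samples)
  expect_error(simulate_gaze_trial(tr, p_defaults, seed = 9,
                                   window_ms = c(-100, 1500)))
  expect_error(simulate_gaze_trial(tr, p_defaults, seed = 9,
                                   window_ms = c(-800, 1501)))
})

test_that("noise-free pupil trace equals the summed impulse responses", {
  tr <- mini_design(170, TRUE)$trials[1, ]
  pp <- generator_params()
  pp$pupil$noise_sd <- 0
  pp$pupil$level_sd <- 0
  pp$pupil$blink_rate <- 0
  rec <- simulate_gaze_trial(tr, pp, seed = 10)
  rec <- simulate_pupil_trial(rec, tr, pp, seed = 10)
  t_ms <- rec$samples$time_ms
  expected <- pp$pupil$base_level +
    (pp$pupil$visual_gain + pp$pupil$sound_gain) *
    (pupil_irf(t_ms - tr$frame1_ms) + pupil_irf(t_ms - tr$frame2_ms))
  expect_equal(rec$samples$pupil, expected, tolerance = 1e-12)
})

test_that("zero sound gain removes the pupil condition difference", {
  pp <- generator_params()
  pp$pupil$sound_gain <- 0
  pp$pupil$blink_rate <- 0
  d <- mini_design(soa_ms = 170, sound = rep(c(TRUE, FALSE), each = 40))
  set.seed(12)
  means <- vapply(seq_len(nrow(d$trials)), function(i) {
    rec <- simulate_gaze_trial(d$trials[i, ], pp)
    rec <- simulate_pupil_trial(rec, d$trials[i, ], pp)
    sel <- rec$samples$time_ms - d$trials$frame1_ms[i] >= 250 &
      rec$samples$time_ms - d$trials$frame1_ms[i] < 1000
    mean(rec$samples$pupil[sel], na.rm = TRUE)
  }, numeric(1))
  pval <- t.test(means[d$trials$sound], means[!d$trials$sound])$p.value
  expect_gt(pval, 0.01)
})

test_that("sound deepens and prolongs the late oculomotor inhibition", {
  tr_snd <- mini_design(170, TRUE)$trials[1, ]
  tr_base <- mini_design(170, FALSE)$trials[1, ]
  t_ms <- tr_snd$frame1_ms + seq(750, 998, by = 2)
  g_snd <- ms_rate_gain(t_ms, tr_snd, p_defaults)
  g_base <- ms_rate_gain(t_ms, tr_base, p_defaults)
  expect_lt(mean(g_snd), mean(g_base))
})

test_that("dataset generation is manifest-reproducible", {
  base <- withr::local_tempdir()
  p_fast <- generator_params()
  dir1 <- file.path(base, "d1")
  dir2 <- file.path(base, "d2")
  generate_dataset(dir1, "E3", n_subjects = 1L, params = p_fast, seed = 21)
  files1 <- list.files(file.path(dir1, "sub-01"), pattern = "tsv$")
  expect_length(files1, 168L)
  regenerate_dataset(file.path(dir1, "manifest.json"), dir2)
  pick <- file.path("sub-01", c("trial-0001.tsv", "trial-0100.tsv",
                                "events.csv", "responses.csv"))
  for (f in pick)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # a parameter change must change the data
  dir3 <- file.path(base, "d3")
  generate_dataset(dir3, "E3", n_subjects = 1L,
                   params = generator_params(ms_base_rate = 2.5), seed = 21)
  expect_false(identical(
    readLines(file.path(dir1, "sub-01", "trial-0001.tsv")),
    readLines(file.path(dir3, "sub-01", "trial-0001.tsv"))))
  expect_error(generate_dataset(file.path(base, "d4"), "E3", n_subjects = 0L))
})
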