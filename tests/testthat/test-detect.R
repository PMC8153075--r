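test_that("the 5-sample window velocity estimator is exact on linear signals", {
  rec <- make_recording(x = rep(1.5, 100))
  v <- compute_velocity(rec)
  expect_true(all(v$vx_deg_s[3:98] == 0))
  expect_true(all(is.na(v$vx_deg_s[c(1, 2, 99, 100)])))
  # ramp at 3 deg/s: x(t) = 3 * t, t in seconds
  t_s <- seq(0, by = 0.002, length.out = 100)
  rec <- make_recording(x = 3 * t_s, y = -2 * t_s)
  v <- compute_velocity(rec)
  expect_equal(v$vx_deg_s[3:98], rep(3, 96), tolerance = 1e-10)
  expect_equal(v$vy_deg_s[3:98], rep(-2, 96), tolerance = 1e-10)
  expect_error(compute_velocity(make_recording(x = rep(0, 4))), "5-sample")
})

test_that("median-based SD matches hand computation and scales covariantly", {
  v <- c(0, 0, 3, 4, -3)
  # median(v^2) = 9, median(v) = 0 -> sigma = 3
  expect_equal(median_sd(v), 3)
  expect_equal(median_sd(-v), median_sd(v))
  expect_equal(median_sd(2 * v), 2 * median_sd(v))
  expect_error(median_sd(rep(NA_real_, 5)), "valid")
  st <- velocity_stats(rep(1, 100))
  expect_equal(st$sigma_x, 0)
  expect_true(st$degenerate)
  st2 <- velocity_stats(c(0, 0, 3, 4, -3))
  expect_equal(st2$threshold_x, 24) # lambda = 8 times sigma = 3
  expect_false(st2$degenerate)
})

test_that("candidate extraction finds supra-threshold runs with half-open extents", {
  vel <- data.frame(time_ms = seq(0, 198, by = 2),
                    vx_deg_s = rep(0, 100), vy_deg_s = rep(0, 100))
  st <- fake_stats(10)
  expect_equal(nrow(detect_candidates(vel, st)), 0L)
  vel$vx_deg_s[21:25] <- 50 # 5 samples = 10 ms
  cand <- detect_candidates(vel, st)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$onset_ms, 40)
  expect_equal(cand$offset_ms, 50)
  expect_equal(cand$duration_ms, 10)
  # an astronomically high threshold removes everything
  expect_equal(nrow(detect_candidates(vel, fake_stats(1e6))), 0L)
  # degenerate stats refuse to detect
  st_bad <- velocity_stats(rep(0, 10))
  expect_error(detect_candidates(vel, st_bad), "degenerate")
})

test_that("detection agrees with a brute-force threshold-crossing oracle", {
  set.seed(42)
  st <- fake_stats(8)
  for (i in 1:1000) {
    n <- sample(50:150, 1)
    vx <- rnorm(n, 0, 4)
    spikes <- sample(n, sample(0:3, 1))
    vx[spikes] <- vx[spikes] + sample(c(-30, 30), length(spikes), TRUE)
    vel <- data.frame(time_ms = seq(0, by = 2, length.out = n),
                      vx_deg_s = vx, vy_deg_s = 0)
    got <- detect_candidates(vel, st, min_samples = 2)
    want <- oracle_candidates(vel$time_ms, vx, 8, 2)
    expect_equal(got$onset_ms, want$onset_ms)
    expect_equal(got$offset_ms, want$offset_ms)
  }
})

test_that("raising lambda yields a subset of the candidates", {
  set.seed(7)
  vx <- rnorm(500, 0, 4)
  vx[c(100:104, 300:310)] <- 60
  vel <- data.frame(time_ms = seq(0, by = 2, length.out = 500),
                    vx_deg_s = vx, vy_deg_s = 0)
  c_lo <- detect_candidates(vel, fake_stats(8))
  c_hi <- detect_candidates(vel, fake_stats(16))
  for (o in c_hi$onset_ms)
    expect_true(any(c_lo$onset_ms <= o & c_lo$offset_ms > o))
})

test_that("duration and interval filters follow the exclusion rules", {
  p <- detection_params()
  cand <- data.frame(onset_ms = c(0, 200, 400, 700),
                     offset_ms = c(2, 210, 515, 740))
  cand$duration_ms <- cand$offset_ms - cand$onset_ms # 2, 10, 115, 40
  kept <- filter_events(cand, p)
  expect_equal(kept$duration_ms, c(10, 40))
  # two valid events 15 ms apart (offset to onset): the earlier survives
  cand2 <- data.frame(onset_ms = c(0, 25), offset_ms = c(10, 40))
  cand2$duration_ms <- c(10, 15)
  kept2 <- filter_events(cand2, p)
  expect_equal(nrow(kept2), 1L)
  expect_equal(kept2$onset_ms, 0)
  # onset-to-onset mode keeps both (25 >= 20)
  p_on <- detection_params(interval_reference = "onset")
  expect_equal(nrow(filter_events(cand2, p_on)), 2L)
  expect_equal(nrow(filter_events(cand2[0, ], p)), 0L)
  expect_error(filter_events(cand2[2:1, ], p), "sorted")
})

test_that("filtering is a subset operation, idempotent, with 20-ms spacing", {
  set.seed(8)
  p <- detection_params()
  for (i in 1:50) {
    n <- sample(1:20, 1)
    onset <- sort(runif(n, 0, 2000))
    dur <- runif(n, 1, 130)
    cand <- data.frame(onset_ms = onset, offset_ms = onset + dur,
                       duration_ms = dur)
    kept <- filter_events(cand, p)
    expect_true(all(kept$onset_ms %in% cand$onset_ms))
    expect_identical(filter_events(kept, p), kept)
    if (nrow(kept) > 1)
      expect_true(all(kept$onset_ms[-1] - kept$offset_ms[-nrow(kept)] >=
                        p$min_interval_ms))
  }
})

test_that("event properties measure displacement and peak speed", {
  # pure horizontal step: (0,0) before, (0.5,0) after
  x <- c(rep(0, 20), seq(0, 0.5, length.out = 5), rep(0.5, 20))
  rec <- make_recording(x = x)
  vel <- compute_velocity(rec)
  ev <- data.frame(onset_ms = rec$samples$time_ms[21],
                   offset_ms = rec$samples$time_ms[25] + 2)
  out <- event_properties(rec, vel, ev)
  expect_equal(out$amplitude_deg, 0.5, tolerance = 1e-9)
  # scaling positions doubles amplitude and peak velocity
  rec2 <- make_recording(x = 2 * x)
  out2 <- event_properties(rec2, compute_velocity(rec2), ev)
  expect_equal(out2$amplitude_deg, 2 * out$amplitude_deg)
  expect_equal(out2$peak_velocity_deg_s, 2 * out$peak_velocity_deg_s)
  # zero-displacement jitter has near-zero amplitude
  xj <- rep(0, 45)
  xj[22:24] <- c(0.05, -0.05, 0.02)
  recj <- make_recording(x = xj)
  outj <- event_properties(recj, compute_velocity(recj), ev)
  expect_lt(outj$amplitude_deg, 0.06)
  # events at the trace edge are flagged
  ev_edge <- data.frame(onset_ms = 0, offset_ms = 6)
  expect_true(event_properties(rec, vel, ev_edge)$edge)
})

test_that("time and space scaling transform detected events covariantly", {
  set.seed(9)
  tr <- mini_design(170, FALSE)$trials[1, ]
  rec <- simulate_gaze_trial(tr, generator_params(), seed = 13)
  det1 <- detect_microsaccades(rec)
  # doubling the spatial scale leaves onsets identical (threshold scales too)
  rec2 <- rec
  rec2$samples$x_deg <- 2 * rec2$samples$x_deg
  rec2$samples$y_deg <- 2 * rec2$samples$y_deg
  det2 <- detect_microsaccades(rec2)
  expect_equal(det2$events$onset_ms, det1$events$onset_ms)
  expect_equal(det2$events$amplitude_deg, 2 * det1$events$amplitude_deg,
               tolerance = 1e-9)
  expect_equal(det2$stats$sigma_x, 2 * det1$stats$sigma_x, tolerance = 1e-9)
})

test_that("main sequence correlation matches the direct formula", {
  ev <- data.frame(amplitude_deg = c(1, 2, 3, 4),
                   peak_velocity_deg_s = c(10, 18, 33, 38))
  ms <- main_sequence(ev)
  a <- ev$amplitude_deg
  v <- ev$peak_velocity_deg_s
  r_hand <- sum((a - mean(a)) * (v - mean(v))) /
    sqrt(sum((a - mean(a))^2) * sum((v - mean(v))^2))
  expect_equal(ms$r, r_hand, tolerance = 1e-12)
  expect_equal(ms$n, 4L)
  # exact line -> r = 1
  ev2 <- data.frame(amplitude_deg = 1:5, peak_velocity_deg_s = 30 * (1:5))
  expect_equal(main_sequence(ev2)$r, 1)
  expect_error(main_sequence(ev2[1:2, ]), "3 events")
  ev3 <- data.frame(amplitude_deg = rep(1, 5), peak_velocity_deg_s = 1:5)
  expect_error(main_sequence(ev3), "variance")
})
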