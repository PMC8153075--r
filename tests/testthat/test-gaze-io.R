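test_that("write/read round-trips recordings and is byte-stable", {
  set.seed(1)
  rec <- make_recording(x = rnorm(50, 0, 0.1), y = rnorm(50, 0, 0.1),
                        pupil = c(rnorm(40, 3000, 20), rep(NA, 10)),
                        t0 = 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_samples(rec, f)
  back <- read_samples(f)
  expect_equal(back$samples$time_ms, rec$samples$time_ms)
  expect_lt(max(abs(back$samples$x_deg - rec$samples$x_deg)), 1e-6)
  expect_lt(max(abs(back$samples$y_deg - rec$samples$y_deg)), 1e-6)
  expect_equal(is.na(back$samples$pupil), is.na(rec$samples$pupil))
  expect_equal(back$sampling_rate, rec$sampling_rate)
  # writing what was read reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_samples(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("an empty recording writes a header-only file that reads back", {
  rec <- gaze_recording(numeric(0), numeric(0), numeric(0), numeric(0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_samples(rec, f)
  expect_true(all(grepl("^#", readLines(f))))
  back <- read_samples(f)
  expect_equal(nrow(back$samples), 0L)
})

test_that("malformed files are rejected with the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rec <- make_recording(x = 1:10 / 10, pupil = rep(3000, 10))
  write_samples(rec, f)
  lines <- readLines(f)
  dup <- lines
  dup[8] <- dup[7] # duplicate a timestamp (body starts at line 6)
  writeLines(dup, f)
  expect_error(read_samples(f), "line 8")
  bad <- lines
  bad[9] <- "not\ta\trow"
  writeLines(bad, f)
  expect_error(read_samples(f), "line 9")
})

test_that("a 3-column file yields an all-missing pupil channel with warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# ternuseye-samples v1",
               "# sampling_rate_hz: 500",
               "# columns: time_ms x_deg y_deg",
               "0.0\t0.1\t0.2", "2.0\t0.1\t0.2"), f)
  expect_warning(rec <- read_samples(f), "pupil")
  expect_true(all(is.na(rec$samples$pupil)))
  expect_equal(nrow(rec$samples), 2L)
})

test_that("non-increasing timestamps and bad headers are rejected", {
  expect_error(gaze_recording(c(0, 2, 2), 1:3, 1:3),
               "strictly increasing")
  expect_error(gaze_recording(c(0, 2, 5), 1:3, 1:3), "constant")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# ternuseye-samples v1", "# columns: time_ms x_deg y_deg"), f)
  expect_error(read_samples(f), "sampling rate")
})

test_that("blink detection pads and merges missing-pupil runs", {
  # no missing samples -> no blinks
  rec <- make_recording(x = rep(0, 500), pupil = rep(3000, 500))
  expect_equal(nrow(detect_blinks(rec)), 0L)
  # one 100-ms missing run padded by 50 ms each side -> 200 ms
  pupil <- rep(3000, 500)
  pupil[101:150] <- NA # 100 ms at 500 Hz
  rec <- make_recording(x = rep(0, 500), pupil = pupil)
  b <- detect_blinks(rec, pad_ms = 50)
  expect_equal(nrow(b), 1L)
  expect_equal(b$end_ms - b$start_ms, 200)
  # two runs 40 ms apart, padded 30 ms each side -> merged
  pupil <- rep(3000, 500)
  pupil[101:110] <- NA
  pupil[131:140] <- NA # gap of 20 samples = 40 ms
  rec <- make_recording(x = rep(0, 500), pupil = pupil)
  b <- detect_blinks(rec, pad_ms = 30)
  expect_equal(nrow(b), 1L)
  # zero pupil counts as missing
  pupil <- rep(3000, 500)
  pupil[201:205] <- 0
  rec <- make_recording(x = rep(0, 500), pupil = pupil)
  expect_equal(nrow(detect_blinks(rec)), 1L)
})

test_that("blink intervals are disjoint, sorted, and cover missing samples", {
  set.seed(3)
  for (rep_i in 1:20) {
    pupil <- rep(3000, 400)
    holes <- sample(380, 8)
    for (h in holes) pupil[h:min(400, h + sample(10, 1))] <- NA
    rec <- make_recording(x = rep(0, 400), pupil = pupil)
    b <- detect_blinks(rec, pad_ms = sample(c(0, 20, 50), 1))
    if (nrow(b) > 1) {
      expect_true(all(diff(b$start_ms) > 0))
      expect_true(all(b$start_ms[-1] >= b$end_ms[-nrow(b)]))
    }
    t_missing <- rec$samples$time_ms[is.na(pupil)]
    covered <- vapply(t_missing, function(t)
      any(t >= b$start_ms & t < b$end_ms), logical(1))
    expect_true(all(covered))
  }
})

test_that("the gaze is the maximal saccade- and blink-free spanning interval", {
  tr <- mini_design(260, FALSE, frame1_ms = 0)$trials[1, ]
  rec <- make_recording(x = rep(0, 500), t0 = -200) # [-200, 800)
  none <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0))
  no_blinks <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  g <- extract_gaze_duration(rec, tr, none, no_blinks)
  expect_true(g$valid)
  expect_equal(g$duration_ms, 1000)
  # a saccade between the frames breaks the spanning fixation
  sac <- data.frame(onset_ms = 100, offset_ms = 120)
  g <- extract_gaze_duration(rec, tr, sac, no_blinks)
  expect_false(g$valid)
  expect_equal(g$exclusion_reason, "no_spanning_fixation")
  # a blink inside the presentation does too
  blink <- data.frame(start_ms = 250, end_ms = 320)
  g <- extract_gaze_duration(rec, tr, none, blink)
  expect_equal(g$exclusion_reason, "no_spanning_fixation")
  # saccades outside the window delimit the gaze instead
  sac2 <- data.frame(onset_ms = c(-150, 600), offset_ms = c(-120, 640))
  g <- extract_gaze_duration(rec, tr, sac2, no_blinks)
  expect_true(g$valid)
  expect_equal(g$gaze_start_ms, -120)
  expect_equal(g$gaze_end_ms, 600)
  # a response inside the gaze invalidates the trial
  g <- extract_gaze_duration(rec, tr, sac2, no_blinks,
                             response_time_ms = 590)
  expect_false(g$valid)
  expect_equal(g$exclusion_reason, "response_during_gaze")
})

test_that("gaze duration is invariant to uniform time translation", {
  tr <- mini_design(170, FALSE, frame1_ms = 0)$trials[1, ]
  rec <- make_recording(x = rep(0, 500), t0 = -200)
  sac <- data.frame(onset_ms = c(-100, 500), offset_ms = c(-80, 520))
  g0 <- extract_gaze_duration(rec, tr, sac, NULL)
  shift <- 730
  tr2 <- tr
  for (col in c("frame1_ms", "frame2_ms", "probe_ms"))
    tr2[[col]] <- tr2[[col]] + shift
  rec2 <- make_recording(x = rep(0, 500), t0 = -200 + shift)
  sac2 <- sac
  sac2$onset_ms <- sac2$onset_ms + shift
  sac2$offset_ms <- sac2$offset_ms + shift
  g2 <- extract_gaze_duration(rec2, tr2, sac2, NULL)
  expect_equal(g2$duration_ms, g0$duration_ms)
})
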