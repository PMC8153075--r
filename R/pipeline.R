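#' Default pipeline configuration
#'
#' Returns the complete configuration of the end-to-end analysis: generator
#' and detection parameter overrides, kernel spec, epoch windows, segment
#' scheme and permutation-test settings. The defaults reproduce the
#' experiment-scale synthetic Experiment-1 analysis (6 virtual participants,
#' full 336-trial design).
#'
#' @param ... Named overrides of top-level fields.
#' @return Configuration list of class `pipeline_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    experiment = "E1",
    n_subjects = 6L,
    seed = 42L,
    data_dir = NULL,          # read an on-disk dataset instead of simulating
    generator = list(),       # overrides passed to generator_params()
    detection = list(),       # overrides passed to detection_params()
    kernel = list(alpha = 1 / 20, support_ms = 200),
    epoch_window_ms = c(-500, 1000),
    test_window_ms = c(0, 1000),
    baseline_window_ms = c(-100, 0),
    segments_ms = c(0, 250, 500, 750, 1000),
    delta_window_ms = c(500, 1000),
    stats = list(n_iterations = 1000, alpha = 0.05),
    out_dir = NULL)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()].
#'
#' @param path Path to a YAML file whose keys mirror [default_config()].
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(default_config, y)
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param data_dir Directory containing `manifest.json` and per-subject
#'   subdirectories.
#' @return List of per-subject lists: `session_id`, `trials`, `behavior`,
#'   `recordings`.
#' @export
read_dataset <- function(data_dir) {
  manifest <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- names(manifest$subjects)
  lapply(subjects, function(sid) {
    sdir <- file.path(data_dir, sid)
    trials <- utils::read.csv(file.path(sdir, "events.csv"))
    behavior <- utils::read.csv(file.path(sdir, "responses.csv"))
    recs <- lapply(sort(list.files(sdir, pattern = "^trial-.*\\.tsv$",
                                   full.names = TRUE)), read_samples)
    list(session_id = sid, trials = trials, behavior = behavior,
         recordings = recs)
  })
}

#' Run the full simulate-detect-analyze pipeline
#'
#' Orchestrates every stage: data generation (or ingestion), microsaccade
#' detection, gaze-duration extraction, kernel-smoothed rate curves with the
#' S1--S4 segment summaries and the paired cluster-based permutation test
#' (sound vs baseline), pupil preprocessing (blink interpolation, session
#' z-normalization, baseline correction) with its cluster test, psychometric
#' fits per participant and pooled, and the per-participant correlation
#' between the sound-induced change in late-window microsaccade rate and the
#' change in group-motion reports. The run is a pure function of the
#' configuration. When `config$out_dir` is set, per-stage CSV/JSON artifacts
#' and a summary report are written there.
#'
#' @param config A `pipeline_config` from [default_config()] or
#'   [read_config()].
#' @return A report list of class `ternus_report`.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  gen <- do.call(generator_params, config$generator)
  det <- do.call(detection_params, config$detection)
  sr <- 500
  dt <- 1000 / sr
  kernel <- smoothing_kernel(alpha = config$kernel$alpha,
                             support_ms = config$kernel$support_ms,
                             step_ms = dt)

  # --- stage: data ---------------------------------------------------------
  if (!is.null(config$data_dir)) {
    subjects <- read_dataset(config$data_dir)
    if (!length(subjects))
      stop("pipeline stage 'ingest': dataset is empty")
  } else {
    if (config$n_subjects < 1) stop("pipeline stage 'ingest': no subjects")
    subjects <- lapply(seq_len(config$n_subjects), function(s) {
      sid <- sprintf("sub-%02d", s)
      design <- build_design(config$experiment,
                             seed = config$seed * 1000L + s)
      ses <- simulate_session(design, gen, session_id = sid,
                              seed = config$seed * 1000L + 500L + s)
      list(session_id = sid, trials = design$trials,
           behavior = ses$behavior, recordings = ses$recordings)
    })
  }

  grid <- seq(config$epoch_window_ms[1], config$epoch_window_ms[2] - dt,
              by = dt)
  test_sel <- grid >= config$test_window_ms[1] &
    grid < config$test_window_ms[2]
  test_grid <- grid[test_sel]
  delta_sel <- grid >= config$delta_window_ms[1] &
    grid < config$delta_window_ms[2]

  per_subj <- lapply(subjects, function(su) {
    sid <- su$session_id
    trials <- su$trials
    # --- detection ---------------------------------------------------------
    detres <- tryCatch(detect_microsaccades(su$recordings, det),
                       error = function(e)
                         stop(sprintf("pipeline stage 'detect' (%s): %s",
                                      sid, conditionMessage(e))))
    events <- detres$events
    # --- gaze durations ----------------------------------------------------
    gaze <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
      rec <- su$recordings[[i]]
      cand <- detres$candidates[detres$candidates$trial_id ==
                                  trials$trial_id[i], , drop = FALSE]
      extract_gaze_duration(rec, trials[i, ], cand, detect_blinks(rec))
    }))
    # --- rate curves per condition -----------------------------------------
    rate_by_cond <- lapply(c(baseline = FALSE, sound = TRUE), function(snd) {
      tsub <- trials[trials$sound == snd, , drop = FALSE]
      esub <- events[events$trial_id %in% tsub$trial_id, , drop = FALSE]
      ras <- event_raster(esub, tsub, lock = "frame1",
                          window_ms = config$epoch_window_ms,
                          sampling_rate = sr)
      rate_curve(ras, sampling_rate = sr, kernel = kernel)
    })
    # --- pupil -------------------------------------------------------------
    pupil_all <- unlist(lapply(su$recordings, function(r) {
      blinks <- detect_blinks(r)
      interpolate_blinks(r$samples$time_ms, r$samples$pupil, blinks)
    }))
    norm <- normalize_session(pupil_all)
    n_per_trial <- vapply(su$recordings, function(r) nrow(r$samples),
                          integer(1))
    offsets <- c(0L, cumsum(n_per_trial))
    pupil_by_cond <- lapply(c(baseline = FALSE, sound = TRUE), function(snd) {
      idx <- which(trials$sound == snd)
      mat <- t(vapply(idx, function(i) {
        z <- norm$z[(offsets[i] + 1):offsets[i + 1]]
        ep <- epoch_trace(su$recordings[[i]]$samples$time_ms, z,
                          trials$frame1_ms[i], config$epoch_window_ms)
        baseline_correct(ep, config$baseline_window_ms)$values
      }, numeric(length(grid))))
      mat
    })
    # --- psychometrics -----------------------------------------------------
    fits <- NULL
    if (!is.null(su$behavior$group_motion)) {
      fits <- lapply(c(baseline = FALSE, sound = TRUE), function(snd) {
        bsub <- su$behavior[su$behavior$sound == snd, ]
        agg <- stats::aggregate(group_motion ~ soa_ms, bsub,
                                function(g) c(k = sum(g), n = length(g)))
        fit_psychometric(agg$soa_ms, agg$group_motion[, "k"],
                         agg$group_motion[, "n"])
      })
    }
    list(session_id = sid, events = events, stats = detres$stats,
         gaze = gaze, rate_by_cond = rate_by_cond,
         pupil_by_cond = pupil_by_cond, fits = fits,
         behavior = su$behavior)
  })

  # --- group level ---------------------------------------------------------
  rate_mat <- function(cond) t(vapply(per_subj, function(p)
    p$rate_by_cond[[cond]]$rate_hz[test_sel], numeric(sum(test_sel))))
  pupil_mat <- function(cond) t(vapply(per_subj, function(p)
    colMeans(p$pupil_by_cond[[cond]])[test_sel], numeric(sum(test_sel))))

  n_subj <- length(per_subj)
  rate_test <- pupil_test <- NULL
  if (n_subj >= 2) {
    rate_test <- permutation_test(rate_mat("sound"), rate_mat("baseline"),
                                  test_grid,
                                  n_iterations = config$stats$n_iterations,
                                  alpha = config$stats$alpha,
                                  seed = config$seed + 1L)
    pupil_test <- permutation_test(pupil_mat("sound"), pupil_mat("baseline"),
                                   test_grid,
                                   n_iterations = config$stats$n_iterations,
                                   alpha = config$stats$alpha,
                                   seed = config$seed + 2L)
  }

  segments <- do.call(rbind, lapply(per_subj, function(p) {
    do.call(rbind, lapply(names(p$rate_by_cond), function(cond) {
      sm <- bin_segments(p$rate_by_cond[[cond]],
                         boundaries_ms = config$segments_ms)
      data.frame(session_id = p$session_id, condition = cond,
                 segment = names(sm), mean_rate_hz = unname(sm),
                 stringsAsFactors = FALSE)
    }))
  }))

  psycho_table <- NULL
  delta_corr <- NULL
  if (!is.null(per_subj[[1]]$fits)) {
    psycho_table <- do.call(rbind, lapply(per_subj, function(p) {
      do.call(rbind, lapply(names(p$fits), function(cond) {
        f <- p$fits[[cond]]
        data.frame(session_id = p$session_id, condition = cond,
                   pse_ms = f$pse, jnd_ms = f$jnd, converged = f$converged,
                   extrapolated = f$extrapolated, stringsAsFactors = FALSE)
      }))
    }))
    # pooled fits across participants
    pooled <- lapply(c(baseline = "baseline", sound = "sound"), function(cond) {
      snd <- cond == "sound"
      beh <- do.call(rbind, lapply(per_subj, function(p)
        p$behavior[p$behavior$sound == snd, c("soa_ms", "group_motion")]))
      agg <- stats::aggregate(group_motion ~ soa_ms, beh,
                              function(g) c(k = sum(g), n = length(g)))
      fit_psychometric(agg$soa_ms, agg$group_motion[, "k"],
                       agg$group_motion[, "n"])
    })
    if (n_subj >= 3) {
      d_rate <- vapply(per_subj, function(p)
        mean(p$rate_by_cond$sound$rate_hz[delta_sel]) -
          mean(p$rate_by_cond$baseline$rate_hz[delta_sel]), numeric(1))
      d_beh <- vapply(per_subj, function(p) {
        b <- p$behavior
        mean(b$group_motion[b$sound]) - mean(b$group_motion[!b$sound])
      }, numeric(1))
      delta_corr <- delta_correlation(d_rate, d_beh, config$delta_window_ms)
    }
  } else pooled <- NULL

  main_seq <- main_sequence(do.call(rbind, lapply(per_subj, function(p)
    p$events[, c("amplitude_deg", "peak_velocity_deg_s")])))

  report <- structure(list(
    config = config, n_subjects = n_subj,
    psychometrics = psycho_table, pooled_fits = pooled,
    gaze = do.call(rbind, lapply(per_subj, function(p) {
      g <- p$gaze
      g$session_id <- p$session_id
      g
    })),
    events = do.call(rbind, lapply(per_subj, function(p) p$events)),
    main_sequence = main_seq,
    rate_curves = per_subj_curves(per_subj, "rate_by_cond"),
    rate_cluster_test = rate_test,
    pupil_cluster_test = pupil_test,
    segments = segments,
    delta_correlation = delta_corr,
    time_ms = test_grid), class = "ternus_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# long-format per-subject per-condition rate curves
per_subj_curves <- function(per_subj, field) {
  do.call(rbind, lapply(per_subj, function(p) {
    do.call(rbind, lapply(names(p[[field]]), function(cond) {
      rc <- p[[field]][[cond]]
      data.frame(session_id = p$session_id, condition = cond,
                 time_ms = rc$time_ms, rate_hz = rc$rate_hz,
                 stringsAsFactors = FALSE)
    }))
  }))
}

#' Write the machine-readable pipeline artifacts
#'
#' Events, rate curves, segment means and psychometric fits as CSV; cluster
#' tests, main-sequence correlation, delta correlation and the config
#' snapshot as JSON.
#'
#' @param report A `ternus_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(report$rate_curves, file.path(out_dir, "rate_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(report$segments, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)
  utils::write.csv(report$gaze, file.path(out_dir, "gaze_durations.csv"),
                   row.names = FALSE)
  if (!is.null(report$psychometrics))
    utils::write.csv(report$psychometrics,
                     file.path(out_dir, "psychometrics.csv"),
                     row.names = FALSE)
  summarize_test <- function(ct) if (is.null(ct)) NULL else
    list(clusters = ct$clusters, threshold = ct$threshold,
         n_iterations = ct$n_iterations, alpha = ct$alpha)
  jsonlite::write_json(list(
    config = unclass(report$config),
    n_subjects = report$n_subjects,
    main_sequence = report$main_sequence,
    pooled_fits = lapply(report$pooled_fits, function(f)
      list(pse_ms = f$pse, jnd_ms = f$jnd, converged = f$converged)),
    rate_cluster_test = summarize_test(report$rate_cluster_test),
    pupil_cluster_test = summarize_test(report$pupil_cluster_test),
    delta_correlation = report$delta_correlation),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.ternus_report <- function(x, ...) {
  cat(sprintf("<ternus_report: %s, %d subjects>\n",
              x$config$experiment, x$n_subjects))
  if (!is.null(x$pooled_fits)) {
    cat(sprintf("  pooled PSE: baseline %.1f ms, sound %.1f ms\n",
                x$pooled_fits$baseline$pse, x$pooled_fits$sound$pse))
  }
  cat(sprintf("  main sequence: r = %.3f (n = %d events)\n",
              x$main_sequence$r, x$main_sequence$n))
  if (!is.null(x$rate_cluster_test) && nrow(x$rate_cluster_test$clusters)) {
    sig <- x$rate_cluster_test$clusters
    sig <- sig[sig$significant, , drop = FALSE]
    for (i in seq_len(nrow(sig)))
      cat(sprintf("  MS-rate cluster: %s, %.0f-%.0f ms, p = %.4f\n",
                  if (sig$sign[i] > 0) "sound > baseline" else "sound < baseline",
                  sig$start_ms[i], sig$end_ms[i], sig$p_value[i]))
  }
  if (!is.null(x$delta_correlation))
    cat(sprintf("  delta-rate vs delta-report: r = %.3f (p = %.3f)\n",
                x$delta_correlation$r, x$delta_correlation$p_value))
  invisible(x)
}
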