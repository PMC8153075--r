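#' Pointwise paired t statistics over time
#'
#' For paired condition matrices A and B (participants x time), the paired t
#' at each time point: `t = mean(d) / (sd(d) / sqrt(n))`, `d = A - B` per
#' participant. Zero-variance time points yield t = 0 with a warning.
#'
#' @param a,b Participants x time matrices on a shared grid (no missing
#'   values, same shape).
#' @return Numeric t series, one value per time point.
#' @export
pointwise_t <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (anyNA(a) || anyNA(b)) stop("paired time series must not contain NA")
  n <- nrow(a)
  if (n < 2) stop("need >= 2 participants")
  d <- a - b
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tser <- m / sqrt(v / n)
  zero <- v <= .Machine$double.eps * 100
  if (any(zero)) {
    warning("zero-variance time point(s); t set to 0")
    tser[zero] <- 0
  }
  tser[!is.finite(tser)] <- 0
  tser
}

#' Threshold a t series into signed clusters
#'
#' Maximal runs of contiguous samples with `t > +threshold` (positive
#' clusters) or `t < -threshold` (negative clusters); the cluster mass is
#' the sum of t within the run. Extents are half-open in time.
#'
#' @param t_series Pointwise t statistics.
#' @param threshold Cluster-forming threshold (> 0).
#' @param time_ms Time grid (same length); constant step assumed.
#' @return data.frame: `start_ms`, `end_ms`, `sign` (+1/-1), `mass`,
#'   `n_samples`; zero rows when nothing is supra-threshold.
#' @export
form_clusters <- function(t_series, threshold, time_ms) {
  stopifnot(threshold > 0, length(t_series) == length(time_ms))
  dt <- if (length(time_ms) > 1) time_ms[2] - time_ms[1] else 0
  out <- list()
  for (sgn in c(1, -1)) {
    above <- sgn * t_series > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i <- starts[j]:ends[j]
      out[[length(out) + 1L]] <-
        data.frame(start_ms = time_ms[starts[j]],
                   end_ms = time_ms[ends[j]] + dt, sign = sgn,
                   mass = sum(t_series[i]), n_samples = length(i))
    }
  }
  if (!length(out))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0),
                      sign = numeric(0), mass = numeric(0),
                      n_samples = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start_ms), , drop = FALSE]
}

# largest |cluster mass| in a t series (both signs); 0 when none
max_abs_cluster_mass <- function(t_series, threshold) {
  m <- 0
  for (sgn in c(1, -1)) {
    idx <- which(sgn * t_series > threshold)
    if (length(idx)) {
      g <- cumsum(c(1L, diff(idx) != 1L))
      m <- max(m, max(abs(rowsum(t_series[idx], g))))
    }
  }
  m
}

#' Cluster-based permutation test for paired time series
#'
#' Nonparametric test of the paired condition difference over time: the
#' observed t series is thresholded at the two-tailed pointwise t critical
#' value (df = n - 1, level `alpha`) into signed clusters with mass = sum of
#' t; the null distribution is the maximum absolute cluster mass over
#' `n_iterations` random per-participant sign flips of the paired
#' differences (exact exchangeability under the paired null). Each observed
#' cluster's p-value is `(1 + #(null >= |mass|)) / (n_iterations + 1)`;
#' a cluster is significant when p < alpha. Fully reproducible given `seed`.
#'
#' @param a,b Participants x time matrices (condition A and B).
#' @param time_ms Shared time grid.
#' @param n_iterations Sign-flip iterations (default 1000; < 100 warns).
#' @param alpha Significance level (default 0.05), also sets the
#'   cluster-forming threshold.
#' @param seed Optional integer seed.
#' @return List of class `cluster_test`: `clusters` (with `p_value` and
#'   `significant`), `t_series`, `time_ms`, `threshold`, `null_max`
#'   (the permutation null of max |mass|), `n_iterations`, `alpha`, `seed`,
#'   `any_significant`.
#' @export
permutation_test <- function(a, b, time_ms, n_iterations = 1000,
                             alpha = 0.05, seed = NULL) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (n_iterations < 100)
    warning("fewer than 100 iterations: p-values will be coarse")
  n <- nrow(a)
  if (is.null(n) || n < 2) stop("need >= 2 participants")
  tobs <- suppressWarnings(pointwise_t(a, b))
  threshold <- stats::qt(1 - alpha / 2, df = n - 1)
  clusters <- form_clusters(tobs, threshold, time_ms)

  if (!is.null(seed)) set.seed(as.integer(seed))
  d <- a - b
  ss <- colSums(d^2) # invariant under sign flips
  signs <- matrix(sample(c(-1, 1), n * n_iterations, replace = TRUE),
                  nrow = n_iterations, ncol = n)
  m_null <- signs %*% d / n
  v_null <- sweep(-n * m_null^2, 2, ss, "+") / (n - 1)
  t_null <- m_null / sqrt(pmax(v_null, .Machine$double.xmin) / n)
  t_null[!is.finite(t_null)] <- 0
  null_max <- vapply(seq_len(n_iterations), function(i)
    max_abs_cluster_mass(t_null[i, ], threshold), numeric(1))

  if (nrow(clusters)) {
    clusters$p_value <- vapply(clusters$mass, function(m)
      (1 + sum(null_max >= abs(m))) / (n_iterations + 1), numeric(1))
    clusters$significant <- clusters$p_value < alpha
  } else {
    clusters$p_value <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(clusters = clusters, t_series = tobs, time_ms = time_ms,
                 threshold = threshold, null_max = null_max,
                 n_iterations = n_iterations, alpha = alpha, seed = seed,
                 any_significant = any(clusters$significant)),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test: %d cluster(s), threshold |t| > %.3f, %d iterations>\n",
              nrow(x$clusters), x$threshold, x$n_iterations))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Correlation between sound-induced oculomotor and behavioral shifts
#'
#' Pearson correlation (two-tailed p from the t transform) between the
#' per-participant sound-minus-baseline difference in mean microsaccade rate
#' over a late window and the corresponding difference in group-motion
#' report proportion.
#'
#' @param delta_ms_rate Per-participant rate differences (events/s).
#' @param delta_behavior Per-participant group-motion proportion differences.
#' @param window_ms The rate window the deltas were computed over (metadata).
#' @return List: `r`, `n`, `p_value`, `window_ms`.
#' @export
delta_correlation <- function(delta_ms_rate, delta_behavior,
                              window_ms = c(500, 1000)) {
  stopifnot(length(delta_ms_rate) == length(delta_behavior))
  n <- length(delta_ms_rate)
  if (n < 3) stop("need >= 3 participants")
  if (stats::sd(delta_ms_rate) == 0 || stats::sd(delta_behavior) == 0)
    stop("zero variance in one of the deltas")
  ct <- stats::cor.test(delta_ms_rate, delta_behavior, method = "pearson")
  list(r = unname(ct$estimate), n = n, p_value = ct$p.value,
       window_ms = window_ms)
}

#' Familywise error rate of the cluster test on null data
#'
#' Simulates paired datasets in which both conditions are i.i.d. draws from
#' the identical process -- kernel-smoothed rate curves built from
#' homogeneous Bernoulli onset rasters -- and reports the fraction of
#' datasets in which the permutation test reports at least one significant
#' cluster. Used to verify that the test controls the familywise type-I
#' error at its alpha level.
#'
#' @param n_datasets Number of simulated null datasets.
#' @param n_participants Participants per dataset (default 17).
#' @param n_trials Trials per participant-condition raster (default 24).
#' @param base_rate Homogeneous event rate, events/s (default 1.5).
#' @param n_iterations Sign-flip iterations per dataset (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the whole schedule.
#' @return List: `fwer` (the false-positive fraction), `n_datasets`,
#'   `any_significant` (logical per dataset).
#' @export
null_cluster_fwer <- function(n_datasets = 200, n_participants = 17,
                              n_trials = 24, base_rate = 1.5,
                              n_iterations = 1000, alpha = 0.05, seed = 1) {
  sr <- 500
  dt <- 1000 / sr
  grid <- seq(0, 1000 - dt, by = dt)
  kern <- smoothing_kernel(step_ms = dt)
  p_bin <- base_rate * dt / 1000
  set.seed(as.integer(seed))
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
  any_sig <- logical(n_datasets)
  for (ds in seq_len(n_datasets)) {
    curves <- function() t(replicate(n_participants, {
      ras <- matrix(stats::rbinom(n_trials * length(grid), 1L, p_bin),
                    n_trials)
      attr(ras, "time_ms") <- grid
      rate_curve(ras, sampling_rate = sr, kernel = kern)$rate_hz
    }))
    a <- curves()
    b <- curves()
    ct <- permutation_test(a, b, grid, n_iterations = n_iterations,
                           alpha = alpha, seed = perm_seeds[ds])
    any_sig[ds] <- ct$any_significant
  }
  list(fwer = mean(any_sig), n_datasets = n_datasets,
       any_significant = any_sig)
}
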