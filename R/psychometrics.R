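#' Fit a two-parameter logistic psychometric function
#'
#' Maximum-likelihood binomial fit of
#' `P(group motion | SOA) = 1 / (1 + exp(-(SOA - mu) / s))`
#' to group-motion counts per SOA level, with no lapse or guess parameters.
#' The point of subjective equality is the 50% point, `PSE = mu`; the
#' just-noticeable difference is half the 25--75% span, `JND = s * ln 3`.
#' Fitting uses the binomial GLM with logit link (iteratively reweighted
#' least squares; deterministic given the data). Degenerate data (all
#' responses identical, or a non-positive fitted slope, i.e. a flat or
#' decreasing curve) yield `converged = FALSE` and no estimates.
#'
#' @param soa_ms SOA levels, ms (>= 2 distinct levels with trials).
#' @param k Group-motion successes per level.
#' @param n Trials per level (> 0).
#' @return Object of class `psychometric_fit`: `mu`, `s`, `pse`, `jnd` (ms),
#'   `n_per_level`, `soa_ms`, `converged`, `extrapolated` (PSE outside the
#'   tested SOA range).
#' @export
fit_psychometric <- function(soa_ms, k, n) {
  stopifnot(length(soa_ms) == length(k), length(k) == length(n))
  if (any(n <= 0)) stop("every level needs n > 0 trials")
  if (any(k < 0 | k > n)) stop("successes must lie in [0, n]")
  if (length(unique(soa_ms)) < 2) stop("need >= 2 distinct SOA levels")

  degenerate <- length(unique(k / n)) == 1L
  fit <- NULL
  if (!degenerate)
    fit <- tryCatch(
      suppressWarnings(stats::glm(cbind(k, n - k) ~ soa_ms,
                                  family = stats::binomial())),
      error = function(e) NULL)
  mu <- s <- NA_real_
  converged <- FALSE
  if (!is.null(fit)) {
    b <- stats::coef(fit)
    if (isTRUE(fit$converged) && all(is.finite(b)) && b[2] > 1e-8) {
      mu <- unname(-b[1] / b[2])
      s <- unname(1 / b[2])
      converged <- TRUE
    }
  }
  structure(list(mu = mu, s = s, pse = mu,
                 jnd = if (converged) s * log(3) else NA_real_,
                 n_per_level = n, soa_ms = soa_ms, converged = converged,
                 extrapolated = converged &&
                   (mu < min(soa_ms) || mu > max(soa_ms))),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<psychometric_fit: PSE %.1f ms, JND %.1f ms%s>\n",
                x$pse, x$jnd,
                if (x$extrapolated) " (PSE extrapolated)" else ""))
  else cat("<psychometric_fit: not converged>\n")
  invisible(x)
}

#' Point of subjective equality
#'
#' The SOA at which the fitted curve crosses 0.5, i.e. the logistic location
#' `mu`. Reported even when it falls outside the tested SOA range (the
#' `extrapolated` flag marks that case); never clipped.
#'
#' @param fit A converged `psychometric_fit`.
#' @return PSE in ms.
#' @export
pse <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) stop("fit did not converge; PSE undefined")
  fit$pse
}

#' Just-noticeable difference
#'
#' Half the span between the 25% and 75% points of the fitted curve;
#' analytically `s * ln 3` for the logistic.
#'
#' @param fit A converged `psychometric_fit`.
#' @return JND in ms.
#' @export
jnd <- function(fit) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) stop("fit did not converge; JND undefined")
  fit$jnd
}

#' Evaluate the fitted psychometric curve
#'
#' @param fit A converged `psychometric_fit`.
#' @param soa_ms SOAs at which to evaluate.
#' @return Predicted group-motion probabilities.
#' @export
predict_psychometric <- function(fit, soa_ms) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (!fit$converged) stop("fit did not converge")
  stats::plogis((soa_ms - fit$mu) / fit$s)
}
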