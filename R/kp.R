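#' Assemble a cumulative release curve from supernatant measurements
#'
#' With complete supernatant replacement at every sampling time, the
#' cumulative release percentage at time t is
#' \eqn{100 \sum_{i \le t} M_i / M_{initial}}: a running sum of the
#' per-interval masses, non-decreasing by construction.
#'
#' @param series A [supernatant_series()].
#' @param tolerance_pct Cumulative totals may exceed 100% by at most this
#'   many percentage points before a data-quality warning is raised
#'   (measurement noise makes small overshoots legitimate).
#' @return A [release_curve()].
#' @examples
#' s <- supernatant_series(times = c(1, 2, 4), masses = c(1, 2, 3),
#'                         m_initial = 12)
#' cumulative_from_supernatants(s)$cumulative_percent  # 8.33, 25, 50
#' @export
cumulative_from_supernatants <- function(series, tolerance_pct = 5) {
  stopifnot(inherits(series, "supernatant_series"))
  cum <- cumsum(series$masses)
  pct <- 100 * cum / series$m_initial
  if (any(pct > 100 + tolerance_pct)) {
    warning(sprintf(
      "cumulative release reaches %.1f%%, more than %g points above 100%%; ",
      max(pct), tolerance_pct),
      "check the loading or the supernatant masses", call. = FALSE)
  }
  release_curve(series$times, cum, series$m_initial)
}

#' Fit the Korsmeyer-Peppas power law to the early release window
#'
#' Fits \eqn{M_t/M_\infty = a\,t^n} to the cumulative release fraction over
#' the first `window_h` hours by ordinary least squares on the linearised
#' form \eqn{\log(M_t/M_\infty) = \log a + n \log t} (natural logs; the
#' slope is invariant to the base and the intercept is back-transformed).
#' Points at t = 0 or with zero release are excluded (their log is
#' undefined); at least 3 usable points are required.
#'
#' The curve's percentages are divided by 100, so `a` is a fraction per
#' hour^n.
#'
#' @param curve A [release_curve()] with times in hours.
#' @param window_h Upper bound of the fitting window in hours. The
#'   conventional early-time window is 6 h, inside which the power law is a
#'   valid approximation of diffusive release (fraction released below
#'   roughly 60%).
#' @return An object of class `kp_fit`: list with `a`, `n`, `r_squared`
#'   (of the linearised fit), `window_h`, `mechanism`
#'   (via [classify_mechanism()]) and `n_points`.
#' @export
fit_korsmeyer_peppas <- function(curve, window_h = 6) {
  stopifnot(inherits(curve, "release_curve"))
  if (window_h <= 0) stop("`window_h` must be positive", call. = FALSE)
  frac <- curve$cumulative_percent / 100
  use <- curve$times > 0 & curve$times <= window_h & frac > 0
  if (sum(use) < 3L) {
    stop("need at least 3 points with t > 0 and positive release ",
         "inside the window to fit the power law", call. = FALSE)
  }
  x <- log(curve$times[use])
  y <- log(frac[use])
  fit <- stats::lm.fit(cbind(1, x), y)
  n <- unname(fit$coefficients[2L])
  a <- exp(unname(fit$coefficients[1L]))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(a = a, n = n, r_squared = r2, window_h = window_h,
                 mechanism = classify_mechanism(n), n_points = sum(use)),
            class = "kp_fit")
}

#' Classify the release mechanism from the Korsmeyer-Peppas exponent
#'
#' For a cylindrical delivery system the exponent thresholds are 0.45 and
#' 0.89: `n <= 0.45` indicates Fickian diffusion (exponents below 0.45
#' still reflect diffusion, with solute-matrix interactions), `0.45 < n <
#' 0.89` anomalous transport (diffusion plus erosion), and `n >= 0.89`
#' erosion-controlled release. The boundaries themselves are assigned to
#' the fickian and erosion classes respectively.
#'
#' @param n Release exponent (finite).
#' @return One of `"fickian"`, `"anomalous"`, `"erosion"` (vectorised).
#' @examples
#' classify_mechanism(c(0.29, 0.54, 0.89))
#' @export
classify_mechanism <- function(n) {
  if (any(!is.finite(n))) stop("`n` must be finite", call. = FALSE)
  out <- ifelse(n <= 0.45, "fickian",
                ifelse(n < 0.89, "anomalous", "erosion"))
  out
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the observations. Can be negative when the prediction
#' is worse than the mean.
#'
#' @param observed Observed values, not all equal.
#' @param predicted Predicted values, same length.
#' @return The statistic.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("`observed` and `predicted` must have equal length >= 2",
         call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 is undefined for constant observations", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' @export
print.kp_fit <- function(x, ...) {
  cat(sprintf(
    "<kp_fit> n = %.4f, a = %.4g h^-n, R^2 = %.4f (%d points <= %g h) -> %s\n",
    x$n, x$a, x$r_squared, x$n_points, x$window_h, x$mechanism))
  invisible(x)
}
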