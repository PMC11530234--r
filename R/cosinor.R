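#' Cosine/sine design basis for a fixed-period cosinor fit
#'
#' Builds the two harmonic regressors \code{cos(2*pi*t/period)} and
#' \code{sin(2*pi*t/period)} used by single-component cosinor regression.
#'
#' @param times Numeric vector of observation times, in hours.
#' @param period Rhythm period in hours (default 24; must be positive).
#' @return A numeric matrix with columns \code{cosw} and \code{sinw}, one row
#'   per time.
#' @examples
#' cosinor_basis(c(0, 6, 12, 18), period = 24)
#' @export
cosinor_basis <- function(times, period = 24) {
  if (!is.numeric(times) || length(times) < 1L)
    stop("`times` must be a non-empty numeric vector")
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0)
    stop("`period` must be a single positive number")
  w <- 2 * pi / period
  cbind(cosw = cos(w * times), sinw = sin(w * times))
}

#' Fixed-period single-component cosinor regression
#'
#' Fits \code{y = M + A * cos(2*pi*(t - phi)/period) + e} by ordinary least
#' squares on the linearized model \code{y ~ cos(wt) + sin(wt)}. The MESOR
#' \code{M} is the intercept, the amplitude is
#' \code{A = sqrt(beta_cos^2 + beta_sin^2)} and the acrophase (hours of the
#' fitted peak, in \code{[0, period)}) is
#' \code{phi = atan2(beta_sin, beta_cos) / w}. Rhythmicity is assessed by the
#' F-test of the cosine/sine pair against the intercept-only model.
#'
#' @param y Numeric response vector (e.g. log-scale expression, activity
#'   counts, heart rate).
#' @param times Observation times in hours, same length as \code{y}.
#' @param period Fixed period in hours (default 24).
#' @return An object of class \code{cosinor_fit}: a list with elements
#'   \code{mesor}, \code{amplitude}, \code{acrophase}, \code{phase_defined},
#'   \code{coefficients} (named \code{beta0}, \code{beta_cos},
#'   \code{beta_sin}), \code{fitted}, \code{residuals}, \code{n}, \code{rss},
#'   \code{sigma2} (residual variance MLE, \code{rss/n}, as required for BIC),
#'   \code{fstat}, \code{p_rhythm} and \code{period}. The F-test denominator
#'   uses the unbiased estimate \code{rss/(n-3)}.
#' @details At least 4 observations are required and the times must not all be
#'   congruent modulo the period (a rank-deficient design is an error). For an
#'   exactly flat fit (\code{A == 0}) the acrophase is reported as 0 with
#'   \code{phase_defined = FALSE}.
#' @examples
#' t <- seq(32, 58, by = 2)
#' y <- 5 + 2 * cos(2 * pi * (t - 10) / 24)
#' fit_cosinor(y, t)
#' @export
fit_cosinor <- function(y, times, period = 24) {
  if (length(y) != length(times))
    stop("`y` and `times` must have the same length")
  if (!all(is.finite(y)) || !all(is.finite(times)))
    stop("`y` and `times` must be finite")
  n <- length(y)
  if (n < 4L)
    stop("cosinor fit requires at least 4 observations")
  X <- cbind(beta0 = rep(1, n), cosinor_basis(times, period))
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("degenerate cosinor design: observation times are congruent modulo ",
         "the period")
  beta <- qr.coef(qx, y)
  names(beta) <- c("beta0", "beta_cos", "beta_sin")
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  ss0 <- sum((y - mean(y))^2)
  df2 <- n - 3L
  msr <- max((ss0 - rss) / 2, 0)
  mse <- rss / df2
  if (rss <= 0 && msr <= 0) {          # exactly constant series
    fstat <- 0; p_rhythm <- 1
  } else if (mse <= 0) {               # perfect rhythmic interpolation
    fstat <- Inf; p_rhythm <- 0
  } else {
    fstat <- msr / mse
    p_rhythm <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  }
  amplitude <- sqrt(beta[["beta_cos"]]^2 + beta[["beta_sin"]]^2)
  # an amplitude at rounding-noise level leaves the acrophase undefined
  phase_defined <- amplitude > .Machine$double.eps^0.75 * max(1, abs(beta[["beta0"]]))
  acrophase <- if (phase_defined) {
    (atan2(beta[["beta_sin"]], beta[["beta_cos"]]) * period / (2 * pi)) %% period
  } else 0
  if (period - acrophase < 1e-9) acrophase <- 0  # peak at phase ~0 wraps cleanly
  structure(list(
    mesor = beta[["beta0"]],
    amplitude = amplitude,
    acrophase = acrophase,
    phase_defined = phase_defined,
    coefficients = beta,
    fitted = fitted,
    residuals = res,
    n = n,
    rss = rss,
    sigma2 = rss / n,
    fstat = fstat,
    p_rhythm = p_rhythm,
    period = period
  ), class = "cosinor_fit")
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "Cosinor fit (period %g h, n = %d)\n  MESOR %.6g  amplitude %.6g  acrophase %.6g h%s\n  rhythmicity F = %.4g, p = %.4g\n",
    x$period, x$n, x$mesor, x$amplitude, x$acrophase,
    if (x$phase_defined) "" else " (undefined: zero amplitude)",
    x$fstat, x$p_rhythm))
  invisible(x)
}
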