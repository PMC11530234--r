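# Two-sample tests used for group comparisons of subject-level cosinor
# parameters: an exact Wilcoxon rank-sum test for MESOR/amplitude and a
# rotation-invariant two-sample Kuiper test for circular acrophases.

# Kuiper V for arbitrary samples: V = sup(Fx - Fy) + sup(Fy - Fx), the ECDF
# differences evaluated at every pooled point (and at the baseline, where the
# difference is zero). Ties are handled by evaluating at the end of each tie
# group.
kuiper_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  ord <- order(z)
  zs <- z[ord]
  wsrt <- c(rep(1 / n1, n1), rep(-1 / n2, n2))[ord]
  keep <- c(diff(zs) > 0, TRUE)
  d <- cumsum(wsrt)[keep]
  max(d, 0) + max(-d, 0)
}

#' Two-sample Kuiper test for circular data with resampled p-value
#'
#' Computes the Kuiper statistic \code{V = D+ + D-} (the sum of the largest
#' ECDF exceedances in both directions over the pooled support) between two
#' samples of circular values, reduced modulo \code{period} before testing.
#' Unlike the Kolmogorov-Smirnov statistic, \code{V} is invariant to a common
#' rotation of both samples, which makes it the appropriate test for
#' acrophases. The p-value is estimated by resampling the pooled values:
#' either random reassignment to groups of the original sizes without
#' replacement (\code{method = "permutation"}, the default) or with
#' replacement (\code{method = "bootstrap"}). The add-one estimator
#' \code{p = (1 + #\{V* >= V\}) / (1 + nboots)} avoids reporting zero.
#'
#' @param x,y Numeric samples of circular values in hours (non-empty).
#' @param nboots Number of resamples (default 10000).
#' @param seed Integer seed for the resampling; the caller's RNG state is
#'   restored afterwards.
#' @param period Circle length in hours (default 24).
#' @param method Resampling scheme, \code{"permutation"} (default) or
#'   \code{"bootstrap"}.
#' @return An object of class \code{kuiper_test}: list with \code{V} (in
#'   \code{[0, 2]}), \code{p}, \code{nboots}, \code{seed} and \code{method}.
#' @examples
#' kuiper_two_sample(c(1, 2, 3), c(13, 14, 15), nboots = 200, seed = 1)
#' @export
kuiper_two_sample <- function(x, y, nboots = 10000, seed = 1L, period = 24,
                              method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must be finite")
  x <- x %% period
  y <- y %% period
  n1 <- length(x); n2 <- length(y)
  V <- kuiper_statistic(x, y)

  z <- c(x, y)
  ord <- order(z)
  zs <- z[ord]
  wsrt <- c(rep(1 / n1, n1), rep(-1 / n2, n2))[ord]
  keep <- c(diff(zs) > 0, TRUE)

  vstar <- with_seed(seed, {
    vapply(seq_len(nboots), function(b) {
      if (method == "permutation") {
        # permuting group labels over the fixed pooled order
        d <- cumsum(sample(wsrt))[keep]
        max(d, 0) + max(-d, 0)
      } else {
        kuiper_statistic(sample(z, n1, replace = TRUE),
                         sample(z, n2, replace = TRUE))
      }
    }, numeric(1))
  })
  p <- (1 + sum(vstar >= V - 1e-12)) / (1 + nboots)
  structure(list(V = V, p = p, nboots = nboots, seed = seed, method = method),
            class = "kuiper_test")
}

#' @export
print.kuiper_test <- function(x, ...) {
  cat(sprintf("Two-sample Kuiper test: V = %.6g, p = %.4g (%s, %d resamples, seed %s)\n",
              x$V, x$p, x$method, x$nboots, format(x$seed)))
  invisible(x)
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Computes the rank-sum statistic \code{W} of the first sample and its exact
#' two-sided p-value from the null permutation distribution of ranks (via the
#' standard counting recursion behind [stats::pwilcox]). The exact path is
#' used when there are no ties and both samples have at most 25 observations;
#' otherwise a normal approximation with midranks, tie correction and
#' continuity correction is used and flagged in the result.
#'
#' @param x,y Numeric samples (non-empty).
#' @return An object of class \code{wilcoxon_test}: list with \code{W} (the
#'   rank-sum of \code{x} in the pooled ranking), \code{p_two_sided},
#'   \code{exact} (logical), \code{ties} (logical) and \code{n} (the two
#'   sample sizes).
#' @examples
#' wilcoxon_exact(c(1, 2), c(3, 4))  # p = 1/3
#' @export
wilcoxon_exact <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("samples must be finite")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && n1 <= 25L && n2 <= 25L
  U <- W - n1 * (n1 + 1) / 2          # Mann-Whitney count
  if (exact) {
    p <- if (U > n1 * n2 / 2) {
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U, n1, n2)
    }
    p <- min(1, p)
  } else {
    ntab <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ntab^3 - ntab) / ((n1 + n2) * (n1 + n2 - 1)))
    zc <- U - mu
    if (sigma2 <= 0) {       # every pooled value tied: no discrimination
      p <- 1
    } else {
      z <- (zc - sign(zc) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
  }
  structure(list(W = W, p_two_sided = p, exact = exact, ties = ties,
                 n = c(n1, n2)), class = "wilcoxon_test")
}

#' @export
print.wilcoxon_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum test (%s%s): W = %g, two-sided p = %.4g\n",
              if (x$exact) "exact" else "normal approximation",
              if (x$ties) ", ties" else "", x$W, x$p_two_sided))
  invisible(x)
}
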