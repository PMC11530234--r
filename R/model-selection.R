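#' Fit the four rhythmicity models for a two-group time course
#'
#' For one gene measured in two groups (young and old), fits by pooled least
#' squares four nested Gaussian models with group-specific intercepts:
#' \describe{
#'   \item{neither}{group means only (2 regression parameters);}
#'   \item{young_only}{cosine/sine terms in the young group only (4);}
#'   \item{old_only}{cosine/sine terms in the old group only (4);}
#'   \item{both}{group-specific intercepts and group-specific cosine/sine
#'     terms (6) — equivalent to two independent cosinor fits.}
#' }
#' Each model has a single shared residual variance, estimated by maximum
#' likelihood (\code{rss/n}), so the parameter count entering the BIC is the
#' number of regression coefficients plus one.
#'
#' @param y_young,y_old Response vectors for the two groups.
#' @param times_young,times_old Observation times (hours) for the two groups.
#' @param period Fixed period in hours (default 24).
#' @return A list of class \code{four_model_fit} with one element per model
#'   (\code{neither}, \code{young_only}, \code{old_only}, \code{both}), each a
#'   list with \code{coefficients}, \code{rss}, \code{k} (parameters including
#'   the variance), \code{loglik} and \code{bic}; plus attributes \code{n} and
#'   \code{period}.
#' @seealso [bic_weights()], [classify_rhythmicity()]
#' @export
fit_four_models <- function(y_young, y_old, times_young, times_old,
                            period = 24) {
  if (length(y_young) != length(times_young) ||
      length(y_old) != length(times_old))
    stop("response and time vectors must have matching lengths per group")
  if (length(y_young) < 1L || length(y_old) < 1L)
    stop("both groups must be non-empty")
  y <- c(y_young, y_old)
  tt <- c(times_young, times_old)
  if (!all(is.finite(y)) || !all(is.finite(tt)))
    stop("responses and times must be finite")
  n <- length(y)
  g_old <- rep(c(0, 1), c(length(y_young), length(y_old)))
  B <- cosinor_basis(tt, period)
  Iy <- 1 - g_old
  Io <- g_old
  designs <- list(
    neither    = cbind(mu_young = Iy, mu_old = Io),
    young_only = cbind(mu_young = Iy, mu_old = Io, Iy * B),
    old_only   = cbind(mu_young = Iy, mu_old = Io, Io * B),
    both       = cbind(mu_young = Iy, mu_old = Io, Iy * B, Io * B)
  )
  models <- lapply(names(designs), function(nm) {
    Xm <- designs[[nm]]
    qx <- qr(Xm)
    if (qx$rank < ncol(Xm))
      stop("degenerate design for model '", nm,
           "': times are congruent modulo the period in a required group")
    beta <- qr.coef(qx, y)
    rss <- sum((y - drop(Xm %*% beta))^2)
    sigma2 <- rss / n
    # exactly-interpolated (noise-free) series: keep the likelihood finite so
    # the most parsimonious perfect-fit model dominates deterministically
    if (sigma2 <= 0) sigma2 <- .Machine$double.xmin
    loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
    k <- ncol(Xm) + 1L
    list(coefficients = beta, rss = rss, k = k, loglik = loglik,
         bic = bic(loglik, k, n))
  })
  names(models) <- names(designs)
  structure(models, class = "four_model_fit", n = n, period = period)
}

#' Bayesian Information Criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters (regression coefficients plus variance).
#' @param n Number of observations (must be at least 1).
#' @return \code{k * log(n) - 2 * loglik}.
#' @export
bic <- function(loglik, k, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a single value >= 1")
  k * log(n) - 2 * loglik
}

#' Schwarz weights for the four rhythmicity models
#'
#' Converts four BIC values into normalized model weights
#' \code{w_i = exp(-dBIC_i/2) / sum_j exp(-dBIC_j/2)} where
#' \code{dBIC_i = BIC_i - min(BIC)}. Subtracting the minimum before
#' exponentiating keeps the computation stable for widely separated BICs. The
#' weights are non-negative, sum to one, and are interpretable as approximate
#' posterior model probabilities.
#'
#' @param bics Either the result of [fit_four_models()] or a numeric vector of
#'   four finite BIC values (named \code{neither}, \code{young_only},
#'   \code{old_only}, \code{both}; default names are applied to an unnamed
#'   vector in that order).
#' @return An object of class \code{model_weights}: a list with numeric
#'   vectors \code{bic} and \code{weights} (both named by model).
#' @examples
#' bic_weights(c(0, 2, 4, 6))
#' @export
bic_weights <- function(bics) {
  if (inherits(bics, "four_model_fit"))
    bics <- vapply(bics, `[[`, numeric(1), "bic")
  if (!is.numeric(bics) || length(bics) != 4L)
    stop("`bics` must be four BIC values or a four_model_fit")
  if (!all(is.finite(bics)))
    stop("all four BIC values must be finite")
  model_names <- c("neither", "young_only", "old_only", "both")
  if (is.null(names(bics))) {
    names(bics) <- model_names
  } else if (!setequal(names(bics), model_names)) {
    stop("named `bics` must use names: ", paste(model_names, collapse = ", "))
  } else {
    bics <- bics[model_names]
  }
  delta <- bics - min(bics)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  structure(list(bic = bics, weights = w), class = "model_weights")
}

#' Classify a gene's rhythmicity from its model weights
#'
#' A gene is assigned the class of the unique model whose Schwarz weight
#' strictly exceeds \code{threshold}; if no weight does, the gene is
#' \code{unclassified}. Because the weights sum to one, at most one can exceed
#' any threshold above 0.5, which is why thresholds at or below 0.5 are
#' rejected.
#'
#' @param weights A \code{model_weights} object (from [bic_weights()]) or a
#'   named numeric vector of four weights.
#' @param threshold Classification threshold, strictly between 0.5 and 1
#'   inclusive of 1 (default 0.75).
#' @return A list of class \code{rhythm_class} with elements \code{label} (one
#'   of \code{rhythmic_both}, \code{rhythmic_young_only},
#'   \code{rhythmic_old_only}, \code{arrhythmic}, \code{unclassified}),
#'   \code{weight} (the winning weight) and \code{threshold}.
#' @export
classify_rhythmicity <- function(weights, threshold = 0.75) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0.5 || threshold > 1)
    stop("`threshold` must lie in (0.5, 1]")
  if (inherits(weights, "model_weights")) weights <- weights$weights
  model_names <- c("neither", "young_only", "old_only", "both")
  if (!is.numeric(weights) || length(weights) != 4L ||
      is.null(names(weights)) || !setequal(names(weights), model_names))
    stop("`weights` must be four weights named: ",
         paste(model_names, collapse = ", "))
  weights <- weights[model_names]
  labels <- c(neither = "arrhythmic", young_only = "rhythmic_young_only",
              old_only = "rhythmic_old_only", both = "rhythmic_both")
  best <- which.max(weights)
  label <- if (weights[best] > threshold) labels[[names(weights)[best]]]
           else "unclassified"
  structure(list(label = label, weight = unname(weights[best]),
                 threshold = threshold), class = "rhythm_class")
}
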