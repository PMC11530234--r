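# Wearable-stream analysis chain: minute aggregation, per-subject fixed-24-h
# cosinor, then group comparisons (Wilcoxon for MESOR/amplitude, Kuiper for
# acrophase).

#' Aggregate a wearable stream to one value per calendar minute
#'
#' Activity counts recorded at sub-minute cadence are summed within each
#' calendar minute (the convention for actigraphy counts); heart-rate or
#' RR-interval streams should use \code{statistic = "mean"}, since summing
#' rates is meaningless. Minutes with no samples are absent from the output
#' (no zero-filling or imputation). Unsorted input is sorted with a warning.
#'
#' @param series Long data.frame with columns \code{subject_id}, \code{group},
#'   \code{timestamp} (POSIXct), \code{value}.
#' @param statistic \code{"sum"} (default, activity counts) or \code{"mean"}.
#' @return A data.frame of the same shape with minute-level timestamps.
#' @export
aggregate_minutes <- function(series, statistic = c("sum", "mean")) {
  statistic <- match.arg(statistic)
  need <- c("subject_id", "group", "timestamp", "value")
  if (!all(need %in% names(series)))
    stop("`series` must have columns: ", paste(need, collapse = ", "))
  if (!inherits(series$timestamp, "POSIXct"))
    stop("`timestamp` must be POSIXct")
  if (!all(is.finite(series$value))) stop("values must be finite")
  time_unsorted <- any(vapply(split(as.numeric(series$timestamp),
                                    series$subject_id),
                              is.unsorted, logical(1)))
  if (time_unsorted)
    warning("input series was not sorted in time within subjects; sorting")
  ord <- order(series$subject_id, series$timestamp)
  if (!identical(ord, seq_len(nrow(series)))) series <- series[ord, ]
  tz <- attr(series$timestamp, "tzone") %||% "UTC"
  minute <- as.POSIXct(floor(as.numeric(series$timestamp) / 60) * 60,
                       origin = "1970-01-01", tz = tz)
  key <- paste(series$subject_id, format(minute, "%Y-%m-%d %H:%M", tz = tz))
  first <- !duplicated(key)
  fun <- if (statistic == "sum") sum else mean
  agg <- tapply(series$value, key, fun)
  out <- data.frame(
    subject_id = series$subject_id[first],
    group = series$group[first],
    timestamp = minute[first],
    value = as.numeric(agg[key[first]]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$subject_id, out$timestamp), ]
}

#' Hours elapsed since midnight of the first recorded day
#'
#' Recalculates timestamps as fractional hours since midnight (00:00, in the
#' timestamps' own timezone) of the first day of measurement, the time axis
#' used for the fixed-24-h cosinor fit.
#'
#' @param timestamps Non-empty POSIXct vector.
#' @param origin Optional explicit origin (POSIXct); defaults to midnight of
#'   the earliest day present.
#' @return Numeric vector of hours.
#' @export
hours_since_start <- function(timestamps, origin = NULL) {
  if (length(timestamps) < 1L) stop("`timestamps` must be non-empty")
  if (!inherits(timestamps, "POSIXct")) stop("`timestamps` must be POSIXct")
  if (is.null(origin)) {
    tz <- attr(timestamps, "tzone") %||% "UTC"
    origin <- as.POSIXct(format(min(timestamps), "%Y-%m-%d", tz = tz), tz = tz)
  }
  as.numeric(difftime(timestamps, origin, units = "hours"))
}

#' Per-subject fixed-24-h cosinor summaries
#'
#' Fits a 24-h cosinor to each subject's series (after converting timestamps
#' to hours since the subject's first midnight) and returns subject-level
#' MESOR, amplitude and acrophase estimates.
#'
#' @param series Long data.frame (\code{subject_id}, \code{group},
#'   \code{timestamp}, \code{value}).
#' @param period Period in hours (default 24).
#' @return data.frame with one row per subject: \code{subject_id},
#'   \code{group}, \code{mesor}, \code{amplitude}, \code{acrophase},
#'   \code{p_rhythm}, \code{n_obs}.
#' @export
subject_cosinor <- function(series, period = 24) {
  split_idx <- split(seq_len(nrow(series)), series$subject_id)
  rows <- lapply(names(split_idx), function(sid) {
    idx <- split_idx[[sid]]
    sub <- series[idx, ]
    h <- hours_since_start(sub$timestamp)
    fit <- fit_cosinor(sub$value, h, period)
    data.frame(subject_id = sid, group = sub$group[1], mesor = fit$mesor,
               amplitude = fit$amplitude, acrophase = fit$acrophase,
               p_rhythm = fit$p_rhythm, n_obs = fit$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare subject-level cosinor parameters between groups
#'
#' Routes MESOR and amplitude to the exact two-sided Wilcoxon rank-sum test
#' and acrophase to the two-sample Kuiper test (circular, resampled p-value).
#'
#' @param summaries data.frame from [subject_cosinor()].
#' @param parameter One of \code{"mesor"}, \code{"amplitude"},
#'   \code{"acrophase"} (alias \code{"phase"}).
#' @param nboots,seed Passed to [kuiper_two_sample()] for the phase test.
#' @param period Circle length for phase comparison (default 24).
#' @return A list with \code{parameter}, \code{test} ("wilcoxon" or
#'   "kuiper"), \code{statistic}, \code{p}, \code{median_young},
#'   \code{median_old} and \code{n} (young, old counts).
#' @export
compare_groups <- function(summaries, parameter, nboots = 10000, seed = 1L,
                           period = 24) {
  aliases <- c(mesor = "mesor", M = "mesor", amplitude = "amplitude",
               A = "amplitude", acrophase = "acrophase", phase = "acrophase")
  if (length(parameter) != 1L || !parameter %in% names(aliases))
    stop("`parameter` must be one of: mesor, amplitude, acrophase")
  parameter <- aliases[[parameter]]
  yv <- summaries[[parameter]][summaries$group == "young"]
  ov <- summaries[[parameter]][summaries$group == "old"]
  if (length(yv) < 2L || length(ov) < 2L)
    stop("need at least 2 subjects per group")
  if (parameter == "acrophase") {
    tst <- kuiper_two_sample(yv, ov, nboots = nboots, seed = seed,
                             period = period)
    statistic <- tst$V; p <- tst$p; test <- "kuiper"
  } else {
    tst <- wilcoxon_exact(yv, ov)
    statistic <- tst$W; p <- tst$p_two_sided; test <- "wilcoxon"
  }
  list(parameter = parameter, test = test, statistic = statistic, p = p,
       median_young = stats::median(yv), median_old = stats::median(ov),
       n = c(young = length(yv), old = length(ov)))
}

#' Run the full wearable-stream group comparison
#'
#' Convenience wrapper: optional minute aggregation, per-subject cosinor fits,
#' and group comparisons of all three cosinor parameters.
#'
#' @param series Long wearable data.frame.
#' @param aggregate \code{"sum"}, \code{"mean"} or \code{"none"} minute
#'   aggregation before fitting.
#' @param nboots,seed Passed to the Kuiper phase test.
#' @return List with \code{subjects} (per-subject summaries) and
#'   \code{comparisons} (a data.frame with one row per parameter).
#' @export
analyze_wearables <- function(series, aggregate = c("sum", "mean", "none"),
                              nboots = 10000, seed = 1L) {
  aggregate <- match.arg(aggregate)
  if (aggregate != "none") series <- aggregate_minutes(series, aggregate)
  subjects <- subject_cosinor(series)
  comparisons <- do.call(rbind, lapply(
    c("mesor", "amplitude", "acrophase"), function(par) {
      cmp <- compare_groups(subjects, par, nboots = nboots, seed = seed)
      data.frame(parameter = par, test = cmp$test, statistic = cmp$statistic,
                 p = cmp$p, median_young = cmp$median_young,
                 median_old = cmp$median_old, stringsAsFactors = FALSE)
    }))
  list(subjects = subjects, comparisons = comparisons)
}
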