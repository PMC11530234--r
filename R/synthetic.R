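#' Configuration for the synthetic serum-entrainment expression simulator
#'
#' Describes the simulated world: a two-group (young/old serum) expression
#' time course sampled every 2 h from 32 to 58 h post serum addition with four
#' serum donors per group, on the log10(1 + normalized count) scale. Genes are
#' partitioned deterministically into four rhythmicity classes; each value is
#' \code{M_g + A_g * cos(2*pi*(t - phi_g)/period) + donor_offset + N(0, noise_sd)}
#' with one additive offset drawn per donor (the baseline difference between
#' sera that heatmap normalization is designed to remove).
#'
#' Within the \code{both}-class block, genes cyclically receive (in order) no
#' effect, a MESOR shift, an amplitude change, or a phase shift in the old
#' group, so ground truth covers all differential scenarios deterministically.
#'
#' @param n_genes Number of genes.
#' @param frac_rhythmic_both,frac_young_only,frac_old_only,frac_neither Class
#'   proportions; must sum to 1. Counts are \code{floor(frac * n_genes)} with
#'   the remainder assigned to \code{neither}.
#' @param timepoints Sampling times in hours post serum addition (default
#'   \code{seq(32, 58, 2)}, 14 points); must be strictly increasing.
#' @param n_donors_per_group Serum donors per group (default 4, labelled A-D).
#' @param period Rhythm period in hours (default 24).
#' @param mesor_range,amplitude_range Uniform ranges for gene-level MESOR and
#'   amplitude, log-expression units.
#' @param noise_sd Gaussian noise SD on the log scale (>= 0).
#' @param donor_offset_sd SD of the per-donor additive intercept.
#' @param delta_mesor,delta_amplitude,delta_phase_hours Effect sizes injected
#'   into the designated differential genes (old group).
#' @param seed Integer seed; the full output is a deterministic function of
#'   the configuration.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_genes = 400,
                              frac_rhythmic_both = 0.25,
                              frac_young_only = 0.25,
                              frac_old_only = 0.25,
                              frac_neither = 0.25,
                              timepoints = seq(32, 58, by = 2),
                              n_donors_per_group = 4,
                              period = 24,
                              mesor_range = c(1, 4),
                              amplitude_range = c(0.5, 1.5),
                              noise_sd = 0.2,
                              donor_offset_sd = 0.1,
                              delta_mesor = 0.5,
                              delta_amplitude = -0.3,
                              delta_phase_hours = 2,
                              seed = 1L) {
  fr <- c(frac_rhythmic_both, frac_young_only, frac_old_only, frac_neither)
  if (any(fr < 0 | fr > 1) || abs(sum(fr) - 1) > 1e-12)
    stop("class fractions must lie in [0, 1] and sum to 1")
  if (n_genes < 0) stop("`n_genes` must be >= 0")
  if (any(diff(timepoints) <= 0)) stop("`timepoints` must be strictly increasing")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (donor_offset_sd < 0) stop("`donor_offset_sd` must be >= 0")
  if (period <= 0) stop("`period` must be positive")
  if (n_donors_per_group < 1) stop("need at least one donor per group")
  if (diff(mesor_range) < 0 || diff(amplitude_range) < 0 ||
      amplitude_range[1] < 0)
    stop("invalid `mesor_range`/`amplitude_range`")
  structure(list(
    n_genes = as.integer(n_genes),
    frac_rhythmic_both = frac_rhythmic_both,
    frac_young_only = frac_young_only,
    frac_old_only = frac_old_only,
    frac_neither = frac_neither,
    timepoints = timepoints,
    n_donors_per_group = as.integer(n_donors_per_group),
    period = period,
    mesor_range = mesor_range,
    amplitude_range = amplitude_range,
    noise_sd = noise_sd,
    donor_offset_sd = donor_offset_sd,
    delta_mesor = delta_mesor,
    delta_amplitude = delta_amplitude,
    delta_phase_hours = delta_phase_hours,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a two-group expression time course with ground truth
#'
#' Draws gene-level parameters, per-donor offsets and observation noise in a
#' single documented RNG sequence seeded at \code{config$seed} (gene MESORs,
#' amplitudes and phases first, then donor offsets, then the noise matrix), so
#' regeneration with the same configuration is bit-identical.
#'
#' @param config A [simulation_config()].
#' @return A list with \code{dataset} (an [expression_dataset()]: genes x
#'   samples matrix plus sample annotation with columns \code{sample_id},
#'   \code{group}, \code{donor}, \code{timepoint_hr}) and \code{truth} (a
#'   data.frame with per-gene class, per-group MESOR/amplitude/acrophase, and
#'   flags plus true values for injected MESOR/amplitude/phase effects).
#' @examples
#' sim <- generate_expression_dataset(simulation_config(n_genes = 10, seed = 1))
#' dim(sim$dataset$values)
#' @export
generate_expression_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("`config` must be a simulation_config")
  n <- config$n_genes
  tp <- config$timepoints
  nd <- config$n_donors_per_group
  donors <- LETTERS[seq_len(nd)]
  groups <- c("young", "old")

  samples <- expand.grid(timepoint_hr = tp, donor = donors, group = groups,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("group", "donor", "timepoint_hr")]
  samples$sample_id <- sprintf("%s_%s_t%02d", samples$group, samples$donor,
                               samples$timepoint_hr)
  samples <- samples[, c("sample_id", "group", "donor", "timepoint_hr")]

  n_both <- floor(config$frac_rhythmic_both * n)
  n_young <- floor(config$frac_young_only * n)
  n_old <- floor(config$frac_old_only * n)
  n_neither <- n - n_both - n_young - n_old
  classes <- rep(c("both", "young_only", "old_only", "neither"),
                 c(n_both, n_young, n_old, n_neither))

  if (n == 0) {
    truth <- data.frame(gene_id = character(), true_class = character(),
                        mesor_young = numeric(), amplitude_young = numeric(),
                        acrophase_young = numeric(), mesor_old = numeric(),
                        amplitude_old = numeric(), acrophase_old = numeric(),
                        has_delta_mesor = logical(), true_delta_mesor = numeric(),
                        has_delta_amplitude = logical(),
                        true_delta_amplitude = numeric(),
                        has_delta_phase = logical(), true_delta_phase = numeric())
    mat <- matrix(numeric(), nrow = 0, ncol = nrow(samples),
                  dimnames = list(NULL, samples$sample_id))
    return(list(dataset = expression_dataset(mat, samples), truth = truth))
  }

  gene_ids <- sprintf("gene_%04d", seq_len(n))

  res <- with_seed(config$seed, {
    mesor <- stats::runif(n, config$mesor_range[1], config$mesor_range[2])
    amp <- stats::runif(n, config$amplitude_range[1], config$amplitude_range[2])
    phase <- stats::runif(n, 0, config$period)
    donor_offset <- stats::rnorm(2 * nd, 0, config$donor_offset_sd)
    noise <- matrix(stats::rnorm(n * nrow(samples), 0, config$noise_sd),
                    nrow = n)
    list(mesor = mesor, amp = amp, phase = phase,
         donor_offset = donor_offset, noise = noise)
  })

  rhythmic_young <- classes %in% c("both", "young_only")
  rhythmic_old <- classes %in% c("both", "old_only")

  m_y <- res$mesor
  a_y <- ifelse(rhythmic_young, res$amp, 0)
  p_y <- ifelse(rhythmic_young, res$phase, 0)
  m_o <- res$mesor
  a_o <- ifelse(rhythmic_old, res$amp, 0)
  p_o <- ifelse(rhythmic_old, res$phase, 0)

  # deterministic cyclic designation of differential effects in both-class
  has_dm <- has_da <- has_dp <- rep(FALSE, n)
  idx_both <- which(classes == "both")
  if (length(idx_both)) {
    slot <- (seq_along(idx_both) - 1) %% 4
    has_dm[idx_both[slot == 1]] <- TRUE
    has_da[idx_both[slot == 2]] <- TRUE
    has_dp[idx_both[slot == 3]] <- TRUE
  }
  m_o[has_dm] <- m_o[has_dm] + config$delta_mesor
  a_o[has_da] <- pmax(a_o[has_da] + config$delta_amplitude, 0)
  p_o[has_dp] <- (p_o[has_dp] + config$delta_phase_hours) %% config$period

  w <- 2 * pi / config$period
  is_old <- samples$group == "old"
  tvec <- samples$timepoint_hr
  signal <- matrix(NA_real_, n, nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  signal[, !is_old] <- outer(seq_len(n), which(!is_old),
    function(i, j) m_y[i] + a_y[i] * cos(w * (tvec[j] - p_y[i])))
  signal[, is_old] <- outer(seq_len(n), which(is_old),
    function(i, j) m_o[i] + a_o[i] * cos(w * (tvec[j] - p_o[i])))

  donor_key <- paste(samples$group, samples$donor, sep = "_")
  donor_levels <- paste(rep(groups, each = nd), rep(donors, 2), sep = "_")
  offsets <- res$donor_offset[match(donor_key, donor_levels)]
  values <- signal + matrix(offsets, n, nrow(samples), byrow = TRUE) + res$noise

  truth <- data.frame(
    gene_id = gene_ids,
    true_class = classes,
    mesor_young = m_y, amplitude_young = a_y, acrophase_young = p_y,
    mesor_old = m_o, amplitude_old = a_o, acrophase_old = p_o,
    has_delta_mesor = has_dm,
    true_delta_mesor = ifelse(has_dm, config$delta_mesor, 0),
    has_delta_amplitude = has_da,
    true_delta_amplitude = ifelse(has_da, config$delta_amplitude, 0),
    has_delta_phase = has_dp,
    true_delta_phase = ifelse(has_dp, config$delta_phase_hours, 0),
    stringsAsFactors = FALSE
  )
  list(dataset = expression_dataset(values, samples), truth = truth)
}

#' Simulate per-subject wearable streams with a diurnal rhythm
#'
#' Emulates wrist-actigraphy-style streams: per subject,
#' \code{value = max(0, mesor + amplitude * cos(2*pi*(t - phase_group - jitter)/24) + noise)}
#' sampled on a regular grid starting at midnight of day 1 (UTC timestamps).
#' Group-level acrophases let a phase-advanced old group be simulated.
#'
#' @param n_subjects_per_group Either a single count for both groups or a
#'   length-2 vector \code{c(young, old)} (default \code{c(7, 8)}).
#' @param days Number of days recorded (>= 1, default 7).
#' @param cadence Sampling interval in seconds; must divide 60 (default 60).
#' @param mesor Baseline level, measurement units (default 2000 counts/min).
#' @param diurnal_amplitude Cosine amplitude (>= 0, default 1000).
#' @param phase_by_group Named numeric \code{c(young=, old=)} acrophases in
#'   hours (default \code{c(young = 16, old = 14)}).
#' @param phase_jitter_sd SD (hours) of per-subject phase jitter (default 0).
#' @param noise_sd SD of additive Gaussian noise (default 200).
#' @param seed Integer seed.
#' @return A long data.frame with columns \code{subject_id}, \code{group},
#'   \code{timestamp} (POSIXct, UTC) and \code{value}.
#' @export
generate_wearable_series <- function(n_subjects_per_group = c(young = 7, old = 8),
                                     days = 7,
                                     cadence = 60,
                                     mesor = 2000,
                                     diurnal_amplitude = 1000,
                                     phase_by_group = c(young = 16, old = 14),
                                     phase_jitter_sd = 0,
                                     noise_sd = 200,
                                     seed = 1L) {
  if (diurnal_amplitude < 0) stop("`diurnal_amplitude` must be >= 0")
  if (days < 1) stop("`days` must be >= 1")
  if (cadence <= 0 || 60 %% cadence != 0)
    stop("`cadence` must be a positive divisor of 60 seconds")
  if (is.null(names(phase_by_group)))
    names(phase_by_group) <- c("young", "old")
  if (!all(c("young", "old") %in% names(phase_by_group)))
    stop("`phase_by_group` must name both 'young' and 'old'")
  if (length(n_subjects_per_group) == 1L)
    n_subjects_per_group <- c(young = n_subjects_per_group,
                              old = n_subjects_per_group)
  ns <- c(young = unname(n_subjects_per_group[[1]]),
          old = unname(n_subjects_per_group[[2]]))

  secs <- seq(0, days * 86400 - cadence, by = cadence)
  origin <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  ts <- origin + secs
  th <- secs / 3600

  with_seed(seed, {
    out <- vector("list", sum(ns))
    k <- 0L
    for (grp in c("young", "old")) {
      for (s in seq_len(ns[[grp]])) {
        k <- k + 1L
        jitter <- stats::rnorm(1, 0, phase_jitter_sd)
        mu <- mesor + diurnal_amplitude *
          cos(2 * pi * (th - phase_by_group[[grp]] - jitter) / 24)
        val <- pmax(0, mu + stats::rnorm(length(th), 0, noise_sd))
        out[[k]] <- data.frame(
          subject_id = sprintf("%s_s%02d", grp, s),
          group = grp,
          timestamp = ts,
          value = val,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  })
}

#' Write/read simulated artifacts as plain text
#'
#' The expression matrix is written as TSV (\code{gene_id} plus one column per
#' sample), the annotation and ground truth as TSVs, and wearable streams as a
#' long CSV with ISO-8601 UTC timestamps. All floats use 12 significant
#' digits, which round-trips the analysis losslessly.
#'
#' @param sim Result of [generate_expression_dataset()].
#' @param matrix_path,annotation_path,truth_path Output TSV paths.
#' @return The output paths, invisibly.
#' @export
write_simulation <- function(sim, matrix_path, annotation_path,
                             truth_path = NULL) {
  write_expression_dataset(sim$dataset, matrix_path, annotation_path)
  if (!is.null(truth_path)) write_tsv_atomic(sim$truth, truth_path)
  invisible(c(matrix_path, annotation_path, truth_path))
}

#' @rdname write_simulation
#' @param series Long wearable data.frame from [generate_wearable_series()].
#' @param path Output CSV path.
#' @export
write_wearable_series <- function(series, path) {
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$value <- fmt_num(out$value)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(pattern = ".tmp_", tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_simulation
#' @export
read_wearable_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "timestamp", "value")
  if (!all(need %in% names(df)))
    stop("wearable CSV must have columns: ", paste(need, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                            "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(df$timestamp)) stop("unparseable timestamps in ", path)
  df
}
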