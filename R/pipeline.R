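#' Pipeline configuration
#'
#' Tuning knobs for the per-gene analysis. \code{phase_gate} decides which
#' genes form the "rhythmic in both groups" family for the phase-difference
#' BH adjustment (and the Fig-style MESOR/amplitude screens): \code{"bic"}
#' (default) gates on the weighted-BIC class \code{rhythmic_both}
#' (\code{w_both > bic_threshold}); \code{"circa"} gates on per-group cosinor
#' rhythmicity q-values (both \code{< q_cutoff}).
#'
#' @param period Fixed rhythm period in hours (default 24).
#' @param bic_threshold Weighted-BIC classification threshold (default 0.75,
#'   strict inequality).
#' @param q_cutoff FDR cutoff used in the subset filters (default 0.05).
#' @param mesor_fc_threshold,amplitude_fc_threshold Strict \code{|log2 FC|}
#'   screen thresholds (defaults 0.25 and 0.1; must be non-negative).
#' @param phase_gate \code{"bic"} or \code{"circa"}.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(period = 24, bic_threshold = 0.75,
                            q_cutoff = 0.05, mesor_fc_threshold = 0.25,
                            amplitude_fc_threshold = 0.1,
                            phase_gate = c("bic", "circa")) {
  phase_gate <- match.arg(phase_gate)
  if (mesor_fc_threshold < 0 || amplitude_fc_threshold < 0)
    stop("log2 fold-change thresholds must be non-negative")
  if (bic_threshold <= 0.5 || bic_threshold > 1)
    stop("`bic_threshold` must lie in (0.5, 1]")
  structure(list(period = period, bic_threshold = bic_threshold,
                 q_cutoff = q_cutoff,
                 mesor_fc_threshold = mesor_fc_threshold,
                 amplitude_fc_threshold = amplitude_fc_threshold,
                 phase_gate = phase_gate), class = "pipeline_config")
}

#' Run the per-gene differential-rhythmicity pipeline
#'
#' For every gene: fits the four rhythmicity models and converts their BICs to
#' Schwarz weights and a class label; fits the joint two-group cosinor model
#' for MESOR/amplitude/phase differences; then adjusts p-values by
#' Benjamini-Hochberg separately per statistic family across genes (per-group
#' rhythmicity and MESOR/amplitude differences across all genes; phase
#' differences across the rhythmic-in-both gate only). Log2 fold changes are
#' derived as \code{log2fc_mesor = (M_old - M_young)/log10(2)} (the MESOR
#' difference of log10-scale values re-expressed in log2 units) and
#' \code{log2fc_amplitude = log2(A_old/A_young)}. Finally the seven gene-subset
#' flags and the \code{|log2 FC|} screens are attached. The result is a
#' deterministic function of the dataset and configuration.
#'
#' Genes whose fits fail or do not converge are flagged via \code{fit_ok} and
#' carry missing statistics; they are never dropped silently.
#'
#' @param dataset An [expression_dataset()] containing both groups.
#' @param config A [pipeline_config()].
#' @return A data.frame (one row per gene) with BICs, weights, class label,
#'   joint-fit estimates and standard errors, p- and q-values, log2 fold
#'   changes, and logical subset/screen flag columns.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config")
  ann <- dataset$samples
  iy <- which(ann$group == "young")
  io <- which(ann$group == "old")
  if (!length(iy) || !length(io))
    stop("dataset must contain both 'young' and 'old' samples")
  ty <- ann$timepoint_hr[iy]
  to <- ann$timepoint_hr[io]
  genes <- rownames(dataset$values)
  ng <- length(genes)

  na6 <- rep(NA_real_, 6)
  rows <- vector("list", ng)
  for (i in seq_len(ng)) {
    yy <- dataset$values[i, iy]
    yo <- dataset$values[i, io]
    fm <- tryCatch(fit_four_models(yy, yo, ty, to, config$period),
                   error = function(e) NULL)
    jf <- tryCatch(fit_joint_cosinor(yy, yo, ty, to, config$period),
                   error = function(e) NULL)
    ok_fm <- !is.null(fm)
    ok_jf <- !is.null(jf) && jf$converged
    if (ok_fm) {
      wts <- bic_weights(fm)
      cls <- classify_rhythmicity(wts, config$bic_threshold)
      bics <- wts$bic; ws <- wts$weights; label <- cls$label
    } else {
      bics <- ws <- stats::setNames(rep(NA_real_, 4),
                                    c("neither", "young_only", "old_only", "both"))
      label <- NA_character_
    }
    est <- if (ok_jf) jf$estimates else stats::setNames(na6, c("k", "k1", "alpha", "alpha1", "phi", "phi1"))
    se <- if (ok_jf) jf$se else est
    pv <- if (ok_jf) jf$p else c(mesor_diff = NA_real_,
                                 amplitude_diff = NA_real_,
                                 phase_diff = NA_real_)
    rows[[i]] <- data.frame(
      gene_id = genes[i],
      bic_neither = bics[["neither"]], bic_young_only = bics[["young_only"]],
      bic_old_only = bics[["old_only"]], bic_both = bics[["both"]],
      w_neither = ws[["neither"]], w_young_only = ws[["young_only"]],
      w_old_only = ws[["old_only"]], w_both = ws[["both"]],
      rhythm_class = label,
      mesor_young = est[["k"]], mesor_diff = est[["k1"]],
      amplitude_young = est[["alpha"]], amplitude_diff = est[["alpha1"]],
      acrophase_young = est[["phi"]], acrophase_diff = est[["phi1"]],
      se_mesor_young = se[["k"]], se_mesor_diff = se[["k1"]],
      se_amplitude_young = se[["alpha"]], se_amplitude_diff = se[["alpha1"]],
      se_acrophase_young = se[["phi"]], se_acrophase_diff = se[["phi1"]],
      p_mesor_diff = pv[["mesor_diff"]],
      p_amplitude_diff = pv[["amplitude_diff"]],
      p_phase_diff = pv[["phase_diff"]],
      p_rhythm_young = if (ok_jf) jf$p_rhythm_young else NA_real_,
      p_rhythm_old = if (ok_jf) jf$p_rhythm_old else NA_real_,
      fit_ok = ok_fm && ok_jf,
      stringsAsFactors = FALSE
    )
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  report$q_rhythm_young <- bh_adjust(report$p_rhythm_young)
  report$q_rhythm_old <- bh_adjust(report$p_rhythm_old)
  report$q_mesor_diff <- bh_adjust(report$p_mesor_diff)
  report$q_amplitude_diff <- bh_adjust(report$p_amplitude_diff)

  gate <- rhythmic_both_gate(report, config)
  p_phase_gated <- ifelse(gate, report$p_phase_diff, NA_real_)
  report$q_phase_diff <- bh_adjust(p_phase_gated)

  report$log2fc_mesor <- report$mesor_diff / log10(2)
  amp_old <- report$amplitude_young + report$amplitude_diff
  report$log2fc_amplitude <- ifelse(
    report$amplitude_young > 0 & amp_old > 0,
    log2(amp_old / report$amplitude_young), NA_real_)

  flags <- subset_flags(report, config)
  screens <- log2fc_screen_flags(report, config)
  cbind(report, flags, screens)
}

# gate: genes considered rhythmic in both groups (family for the phase test
# and the Fig-2-style screens)
rhythmic_both_gate <- function(report, config) {
  if (config$phase_gate == "bic") {
    !is.na(report$rhythm_class) & report$rhythm_class == "rhythmic_both"
  } else {
    !is.na(report$q_rhythm_young) & !is.na(report$q_rhythm_old) &
      report$q_rhythm_young < config$q_cutoff &
      report$q_rhythm_old < config$q_cutoff
  }
}

# the seven printed subset conjunctions, as pure functions of report columns
subset_flags <- function(report, config = pipeline_config()) {
  q <- config$q_cutoff
  thr <- config$bic_threshold
  rb_q <- !is.na(report$q_rhythm_young) & !is.na(report$q_rhythm_old) &
    report$q_rhythm_young < q & report$q_rhythm_old < q
  dm_q <- rb_q & !is.na(report$q_mesor_diff) & report$q_mesor_diff < q
  dp_q <- rb_q & !is.na(report$q_phase_diff) & report$q_phase_diff < q
  data.frame(
    subset_decreased_mesor = dm_q & report$mesor_diff < 0,
    subset_increased_mesor = dm_q & report$mesor_diff > 0,
    subset_phase_advance = dp_q & report$acrophase_diff < 0,
    subset_phase_delay = dp_q & report$acrophase_diff > 0,
    subset_loss_rhythmicity = !is.na(report$w_young_only) &
      report$w_young_only > thr,
    subset_gain_rhythmicity = !is.na(report$w_old_only) &
      report$w_old_only > thr,
    subset_rhythmic_both = !is.na(report$w_both) & report$w_both > thr
  )
}

# |log2 FC| screens layered over the q<cutoff + direction calls among genes
# rhythmic in both groups (per the configured gate); strict inequalities
log2fc_screen_flags <- function(report, config = pipeline_config()) {
  q <- config$q_cutoff
  gate <- rhythmic_both_gate(report, config)
  dm <- gate & !is.na(report$q_mesor_diff) & report$q_mesor_diff < q
  da <- gate & !is.na(report$q_amplitude_diff) & report$q_amplitude_diff < q
  lfc_m <- report$log2fc_mesor
  lfc_a <- report$log2fc_amplitude
  data.frame(
    screen_mesor_up = dm & report$mesor_diff > 0 & !is.na(lfc_m) &
      abs(lfc_m) > config$mesor_fc_threshold,
    screen_mesor_down = dm & report$mesor_diff < 0 & !is.na(lfc_m) &
      abs(lfc_m) > config$mesor_fc_threshold,
    screen_amplitude_up = da & report$amplitude_diff > 0 & !is.na(lfc_a) &
      abs(lfc_a) > config$amplitude_fc_threshold,
    screen_amplitude_down = da & report$amplitude_diff < 0 & !is.na(lfc_a) &
      abs(lfc_a) > config$amplitude_fc_threshold
  )
}

#' The seven gene-subset filters
#'
#' Re-derives the seven published subset conjunctions from a gene report and
#' returns the gene lists (suitable as enrichment-tool input):
#' \enumerate{
#'   \item decreased MESOR in old: rhythmic q < cutoff in both groups, MESOR
#'     difference q < cutoff, MESOR difference (old - young) < 0;
#'   \item increased MESOR in old: as (1) with difference > 0;
#'   \item phase advance in old: rhythmic q < cutoff in both groups, phase
#'     difference q < cutoff, phase difference < 0;
#'   \item phase delay in old: as (3) with difference > 0;
#'   \item loss of rhythmicity: weight of the young-only model > threshold;
#'   \item gain of rhythmicity: weight of the old-only model > threshold;
#'   \item rhythmic in both: weight of the both model > threshold.
#' }
#'
#' @param report Gene report from [run_pipeline()].
#' @param config A [pipeline_config()] (thresholds; default as published).
#' @return Named list of seven character vectors of gene ids.
#' @export
subset_filters <- function(report, config = pipeline_config()) {
  flags <- subset_flags(report, config)
  lapply(flags, function(f) report$gene_id[f])
}

#' MESOR/amplitude |log2 FC| screens
#'
#' Applies the strict \code{|log2 FC|} screens on top of the
#' q-significant directional MESOR/amplitude calls among genes rhythmic in
#' both groups. Boundary values (e.g. \code{|log2 FC|} exactly at the
#' threshold) are excluded.
#'
#' @inheritParams subset_filters
#' @param mesor_threshold,amplitude_threshold Strict screen thresholds
#'   (defaults 0.25 and 0.1; must be non-negative).
#' @return Named list of four character vectors of gene ids
#'   (\code{screen_mesor_up}, \code{screen_mesor_down},
#'   \code{screen_amplitude_up}, \code{screen_amplitude_down}).
#' @export
log2fc_screens <- function(report, mesor_threshold = 0.25,
                           amplitude_threshold = 0.1,
                           config = pipeline_config()) {
  if (mesor_threshold < 0 || amplitude_threshold < 0)
    stop("screen thresholds must be non-negative")
  config$mesor_fc_threshold <- mesor_threshold
  config$amplitude_fc_threshold <- amplitude_threshold
  flags <- log2fc_screen_flags(report, config)
  lapply(flags, function(f) report$gene_id[f])
}

#' Three-round heatmap normalization
#'
#' Normalizes a two-group expression time course for heatmap display, per
#' gene: (1) mean-center the values within each age group x serum donor, to
#' remove baseline differences between sera; (2) collapse donors by averaging
#' replicates at each group x timepoint; (3) Z-score (sample SD) across
#' timepoints within each group. Display-only: never used by the statistics.
#'
#' @param dataset An [expression_dataset()]; every group x timepoint cell must
#'   contain at least one sample.
#' @return A data.frame with columns \code{gene_id}, \code{group},
#'   \code{constant} (flag: zero variance after collapsing, row emitted as
#'   all zeros) and one column \code{t<hours>} per timepoint.
#' @export
heatmap_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  ann <- dataset$samples
  groups <- c("young", "old")
  tps <- sort(unique(ann$timepoint_hr))
  for (g in groups) {
    for (tp in tps) {
      if (!any(ann$group == g & ann$timepoint_hr == tp))
        stop("no samples for group '", g, "' at timepoint ", tp, " h")
    }
  }
  donor_key <- paste(ann$group, ann$donor)
  gt_key <- paste(ann$group, ann$timepoint_hr)
  ng <- nrow(dataset$values)
  out <- vector("list", 2L * ng)
  k <- 0L
  for (i in seq_len(ng)) {
    v <- dataset$values[i, ]
    # round 1: per group x donor mean-centering
    centered <- v - stats::ave(v, donor_key)
    # round 2: collapse replicates per group x timepoint
    for (g in groups) {
      sel <- ann$group == g
      m <- tapply(centered[sel], ann$timepoint_hr[sel], mean)
      m <- as.numeric(m[as.character(tps)])
      # round 3: Z-score across timepoints (sample SD)
      s <- stats::sd(m)
      constant <- !is.finite(s) || s == 0
      z <- if (constant) rep(0, length(m)) else (m - mean(m)) / s
      k <- k + 1L
      row <- data.frame(gene_id = rownames(dataset$values)[i], group = g,
                        constant = constant, stringsAsFactors = FALSE)
      row[paste0("t", tps)] <- as.list(z)
      out[[k]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
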