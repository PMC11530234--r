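# constructed gene report rows for pure filter-logic checks
mk_report_row <- function(gene_id = "g1", q_ry = 1, q_ro = 1, q_dm = 1,
                          q_da = 1, q_dp = NA, dm = 0, da = 0, dp = 0,
                          w_y = 0, w_o = 0, w_b = 0,
                          rhythm_class = "unclassified", a_y = 1,
                          lfc_m = NULL, lfc_a = NULL) {
  data.frame(gene_id = gene_id, q_rhythm_young = q_ry, q_rhythm_old = q_ro,
             q_mesor_diff = q_dm, q_amplitude_diff = q_da, q_phase_diff = q_dp,
             mesor_diff = dm, amplitude_diff = da, acrophase_diff = dp,
             w_neither = max(0, 1 - w_y - w_o - w_b), w_young_only = w_y,
             w_old_only = w_o, w_both = w_b, rhythm_class = rhythm_class,
             amplitude_young = a_y,
             log2fc_mesor = lfc_m %||% (dm / log10(2)),
             log2fc_amplitude = lfc_a %||%
               ifelse(a_y > 0 & a_y + da > 0, log2((a_y + da) / a_y), NA),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the seven subset conjunctions implement the printed criteria", {
  rows <- rbind(
    mk_report_row("dec_mesor", q_ry = 0.01, q_ro = 0.02, q_dm = 0.03, dm = -0.4),
    mk_report_row("inc_mesor", q_ry = 0.01, q_ro = 0.02, q_dm = 0.03, dm = 0.4),
    mk_report_row("not_rhythmic", q_ry = 0.2, q_ro = 0.02, q_dm = 0.03, dm = -0.4),
    mk_report_row("adv_phase", q_ry = 0.01, q_ro = 0.01, q_dp = 0.01, dp = -1.5),
    mk_report_row("del_phase", q_ry = 0.01, q_ro = 0.01, q_dp = 0.01, dp = 1.5),
    mk_report_row("loss", w_y = 0.8),
    mk_report_row("gain", w_o = 0.8),
    mk_report_row("both", w_b = 0.8, rhythm_class = "rhythmic_both"),
    mk_report_row("boundary_w", w_y = 0.75),     # exactly at threshold: excluded
    mk_report_row("q_boundary", q_ry = 0.01, q_ro = 0.01, q_dm = 0.05, dm = -0.4)
  )
  subs <- subset_filters(rows)
  expect_equal(subs$subset_decreased_mesor, "dec_mesor")
  expect_equal(subs$subset_increased_mesor, "inc_mesor")
  expect_equal(subs$subset_phase_advance, "adv_phase")
  expect_equal(subs$subset_phase_delay, "del_phase")
  expect_equal(subs$subset_loss_rhythmicity, "loss")
  expect_equal(subs$subset_gain_rhythmicity, "gain")
  expect_equal(subs$subset_rhythmic_both, "both")
  # loss criterion is independent of any q-value
  loss_any_q <- mk_report_row("g", q_ry = 0.9, q_ro = 0.9, w_y = 0.8)
  expect_equal(subset_filters(loss_any_q)$subset_loss_rhythmicity, "g")
  # MESOR subsets (1) vs (2) and phase subsets (3) vs (4) are disjoint
  expect_length(intersect(subs$subset_decreased_mesor,
                          subs$subset_increased_mesor), 0)
  expect_length(intersect(subs$subset_phase_advance,
                          subs$subset_phase_delay), 0)
})

test_that("log2 FC screens are strict and layered on the q + direction calls", {
  # |log2 FC| exactly at the threshold must be excluded
  rows <- rbind(
    mk_report_row("at_bound", q_dm = 0.01, dm = 0.2, lfc_m = 0.25, w_b = 0.8,
                  rhythm_class = "rhythmic_both"),
    mk_report_row("above", q_dm = 0.01, dm = 0.3 * log10(2) + 1e-9, w_b = 0.8,
                  rhythm_class = "rhythmic_both"),
    mk_report_row("below_dir", q_dm = 0.01, dm = -0.4 * log10(2), w_b = 0.8,
                  rhythm_class = "rhythmic_both"),
    mk_report_row("no_call", q_dm = 0.2, dm = 0.4 * log10(2), w_b = 0.8,
                  rhythm_class = "rhythmic_both"),
    mk_report_row("amp_dn", q_da = 0.01, da = -0.5, a_y = 1, w_b = 0.8,
                  rhythm_class = "rhythmic_both"),
    mk_report_row("amp_no_q", q_da = 0.2, da = -0.5, a_y = 1, w_b = 0.8,
                  rhythm_class = "rhythmic_both")
  )
  scr <- log2fc_screens(rows)
  expect_equal(scr$screen_mesor_up, "above")
  expect_equal(scr$screen_mesor_down, "below_dir")
  expect_false("at_bound" %in% unlist(scr))
  expect_false("no_call" %in% unlist(scr))
  # log2(0.5/1) = -1, passes the 0.1 threshold, only with the q call
  expect_equal(scr$screen_amplitude_down, "amp_dn")
  expect_error(log2fc_screens(rows, mesor_threshold = -0.1), "non-negative")
})

test_that("expression TSV round-trip is the identity and reconciles shuffles", {
  sim <- generate_expression_dataset(simulation_config(n_genes = 8, seed = 12))
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  mp <- file.path(dir, "matrix.tsv"); ap <- file.path(dir, "annotation.tsv")
  write_expression_dataset(sim$dataset, mp, ap)
  back <- load_expression(mp, ap)
  expect_equal(back$values, sim$dataset$values, tolerance = 1e-10)
  expect_equal(back$samples, sim$dataset$samples)
  # shuffled annotation rows are reconciled by sample_id
  ann <- sim$dataset$samples[sample(nrow(sim$dataset$samples)), ]
  ap2 <- file.path(dir, "annotation_shuffled.tsv")
  utils::write.table(ann, ap2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- load_expression(mp, ap2)
  expect_equal(back2$samples, sim$dataset$samples)
  # a missing annotation row names the offending sample
  ap3 <- file.path(dir, "annotation_missing.tsv")
  utils::write.table(ann[-1, ], ap3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_expression(mp, ap3), ann$sample_id[1], fixed = TRUE)
})

test_that("dataset construction rejects duplicates and unknown groups", {
  vals <- matrix(rnorm(8), 2, 4,
                 dimnames = list(c("g1", "g1"),
                                 c("young_A_t32", "young_A_t34",
                                   "old_A_t32", "old_A_t34")))
  ann <- data.frame(sample_id = colnames(vals),
                    group = rep(c("young", "old"), each = 2),
                    donor = "A", timepoint_hr = c(32, 34, 32, 34))
  expect_error(expression_dataset(vals, ann), "duplicate gene ids: g1")
  rownames(vals) <- c("g1", "g2")
  ann_bad <- ann; ann_bad$group[1] <- "middle"
  expect_error(expression_dataset(vals, ann_bad), "unknown group")
  expect_no_error(expression_dataset(vals, ann))
})

test_that("pipeline output is complete, deterministic and order-invariant", {
  cfg <- simulation_config(n_genes = 24, noise_sd = 0.2, donor_offset_sd = 0,
                           seed = 17)
  sim <- generate_expression_dataset(cfg)
  rep1 <- run_pipeline(sim$dataset)
  expect_equal(nrow(rep1), 24)
  expect_true(all(rep1$fit_ok))
  expect_identical(rep1, run_pipeline(sim$dataset))
  # permuting sample columns changes nothing
  perm <- sample(ncol(sim$dataset$values))
  ds_perm <- expression_dataset(sim$dataset$values[, perm],
                                sim$dataset$samples[perm, ])
  rep2 <- run_pipeline(ds_perm)
  expect_equal(rep2, rep1, tolerance = 1e-9)
  # weights sum to one; flags recomputed from columns match the stored flags
  wsum <- rep1$w_neither + rep1$w_young_only + rep1$w_old_only + rep1$w_both
  expect_equal(wsum, rep(1, 24), tolerance = 1e-12)
  flag_cols <- grep("^(subset|screen)_", names(rep1), value = TRUE)
  relists <- c(subset_filters(rep1), log2fc_screens(rep1))
  for (nm in flag_cols)
    expect_equal(rep1$gene_id[rep1[[nm]]], relists[[nm]], info = nm)
})

test_that("an old group copied from young yields no differential calls", {
  sim <- generate_expression_dataset(
    simulation_config(n_genes = 12, frac_rhythmic_both = 1,
                      frac_young_only = 0, frac_old_only = 0, frac_neither = 0,
                      delta_mesor = 0, delta_amplitude = 0,
                      delta_phase_hours = 0, donor_offset_sd = 0, seed = 23))
  vals <- sim$dataset$values
  ann <- sim$dataset$samples
  vals[, ann$group == "old"] <- vals[, ann$group == "young"]
  rep <- run_pipeline(expression_dataset(vals, ann))
  expect_equal(rep$p_mesor_diff, rep(1, 12))
  expect_equal(rep$p_amplitude_diff, rep(1, 12))
  expect_equal(rep$p_phase_diff, rep(1, 12))
  expect_false(any(rep$subset_decreased_mesor | rep$subset_increased_mesor |
                     rep$subset_phase_advance | rep$subset_phase_delay))
  expect_false(any(unlist(rep[grep("^screen_", names(rep))])))
})

test_that("heatmap normalization satisfies its contract", {
  sim <- generate_expression_dataset(simulation_config(n_genes = 6, seed = 31))
  hm <- heatmap_normalize(sim$dataset)
  expect_equal(nrow(hm), 12)  # gene x group
  zcols <- grep("^t\\d+$", names(hm), value = TRUE)
  expect_length(zcols, 14)
  z <- as.matrix(hm[zcols])
  expect_equal(unname(rowMeans(z)), rep(0, 12), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 12), tolerance = 1e-9)
  # adding a constant to one donor's samples is removed by round 1
  vals <- sim$dataset$values
  ann <- sim$dataset$samples
  sel <- ann$group == "old" & ann$donor == "B"
  vals[, sel] <- vals[, sel] + 5
  hm2 <- heatmap_normalize(expression_dataset(vals, ann))
  expect_equal(hm2, hm, tolerance = 1e-9)
})

test_that("heatmap normalization handles degenerate inputs explicitly", {
  sim <- generate_expression_dataset(
    simulation_config(n_genes = 2, frac_rhythmic_both = 0, frac_young_only = 0,
                      frac_old_only = 0, frac_neither = 1, noise_sd = 0,
                      donor_offset_sd = 0, seed = 2))
  hm <- heatmap_normalize(sim$dataset)  # constant genes
  expect_true(all(hm$constant))
  zcols <- grep("^t\\d+$", names(hm), value = TRUE)
  expect_true(all(as.matrix(hm[zcols]) == 0))
  # a missing group x timepoint cell is a named error
  ds <- sim$dataset
  keep <- !(ds$samples$group == "old" & ds$samples$timepoint_hr == 40)
  ds_sub <- expression_dataset(ds$values[, keep], ds$samples[keep, ])
  expect_error(heatmap_normalize(ds_sub), "group 'old' at timepoint 40")
})
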