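test_that("noise-free generation reproduces the cosine model exactly", {
  cfg <- simulation_config(n_genes = 1, frac_rhythmic_both = 1,
                           frac_young_only = 0, frac_old_only = 0,
                           frac_neither = 0, noise_sd = 0,
                           donor_offset_sd = 0, delta_mesor = 0,
                           delta_amplitude = 0, delta_phase_hours = 0,
                           mesor_range = c(5, 5), amplitude_range = c(2, 2),
                           seed = 4)
  sim <- generate_expression_dataset(cfg)
  tr <- sim$truth
  expect_equal(tr$mesor_young, 5)
  expect_equal(tr$amplitude_young, 2)
  ann <- sim$dataset$samples
  expected <- cosine_signal(ann$timepoint_hr, 5, 2, tr$acrophase_young)
  expect_equal(unname(sim$dataset$values[1, ]), expected, tolerance = 1e-12)
})

test_that("design dimensions and sample naming follow the study layout", {
  sim <- generate_expression_dataset(simulation_config(n_genes = 100, seed = 1))
  expect_equal(dim(sim$dataset$values), c(100, 2 * 4 * 14))
  ann <- sim$dataset$samples
  expect_equal(sum(ann$group == "young"), 56)
  expect_equal(sort(unique(ann$donor)), LETTERS[1:4])
  expect_equal(sort(unique(ann$timepoint_hr)), seq(32, 58, 2))
  expect_true(all(grepl("^(young|old)_[A-D]_t\\d{2}$", ann$sample_id)))
})

test_that("same seed is bit-identical, different seeds differ", {
  a <- generate_expression_dataset(simulation_config(n_genes = 30, seed = 99))
  b <- generate_expression_dataset(simulation_config(n_genes = 30, seed = 99))
  expect_identical(a$dataset$values, b$dataset$values)
  expect_identical(a$truth, b$truth)
  c_ <- generate_expression_dataset(simulation_config(n_genes = 30, seed = 100))
  expect_true(any(a$dataset$values != c_$dataset$values))
})

test_that("class counts follow the deterministic floor rule and truth invariants", {
  cfg <- simulation_config(n_genes = 101, frac_rhythmic_both = 0.30,
                           frac_young_only = 0.30, frac_old_only = 0.25,
                           frac_neither = 0.15, seed = 6)
  tr <- generate_expression_dataset(cfg)$truth
  counts <- table(tr$true_class)
  expect_equal(unname(counts[["both"]]), floor(0.30 * 101))
  expect_equal(unname(counts[["young_only"]]), floor(0.30 * 101))
  expect_equal(unname(counts[["old_only"]]), floor(0.25 * 101))
  expect_equal(unname(counts[["neither"]]), 101 - 30 - 30 - 25)
  # invariants: non-negative amplitudes, phases in [0, 24), flat where flat
  expect_true(all(tr$amplitude_young >= 0 & tr$amplitude_old >= 0))
  expect_true(all(tr$acrophase_young >= 0 & tr$acrophase_young < 24))
  expect_true(all(tr$acrophase_old >= 0 & tr$acrophase_old < 24))
  flat <- tr$true_class == "neither"
  expect_true(all(tr$amplitude_young[flat] == 0 & tr$amplitude_old[flat] == 0))
  only_y <- tr$true_class == "young_only"
  expect_true(all(tr$amplitude_old[only_y] == 0))
  # differential effects only ever land on both-class genes
  hit <- tr$has_delta_mesor | tr$has_delta_amplitude | tr$has_delta_phase
  expect_true(all(tr$true_class[hit] == "both"))
})

test_that("configuration validation catches inconsistent worlds", {
  expect_error(simulation_config(frac_rhythmic_both = 0.5, frac_young_only = 0.5,
                                 frac_old_only = 0.5, frac_neither = 0.5),
               "sum to 1")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(timepoints = c(32, 32, 34)), "increasing")
  expect_error(generate_expression_dataset(list()), "simulation_config")
})

test_that("an empty gene set yields an empty dataset and truth", {
  sim <- generate_expression_dataset(simulation_config(n_genes = 0))
  expect_equal(nrow(sim$dataset$values), 0)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(ncol(sim$dataset$values), 112)
})

test_that("wearable streams honor subject counts, cadence and group phases", {
  ser <- generate_wearable_series(n_subjects_per_group = c(young = 7, old = 8),
                                  days = 2, cadence = 60, phase_jitter_sd = 0,
                                  noise_sd = 0, seed = 1)
  expect_equal(length(unique(ser$subject_id)), 15)
  expect_equal(unname(table(ser$subject_id)[1]), 2880)
  # zero-noise recovery of the group acrophases through the analysis chain
  subj <- subject_cosinor(ser)
  expect_equal(unname(subj$acrophase[subj$group == "young"]), rep(16, 7),
               tolerance = 1e-9)
  expect_equal(unname(subj$acrophase[subj$group == "old"]), rep(14, 8),
               tolerance = 1e-9)
  expect_error(generate_wearable_series(diurnal_amplitude = -5), ">= 0")
  expect_error(generate_wearable_series(cadence = 7), "divisor")
})

test_that("wearable CSV round-trips through write/read", {
  ser <- generate_wearable_series(n_subjects_per_group = 2, days = 1,
                                  noise_sd = 50, seed = 3)
  path <- file.path(tempdir(), "wear.csv")
  write_wearable_series(ser, path)
  back <- read_wearable_series(path)
  expect_equal(back$subject_id, ser$subject_id)
  expect_equal(as.numeric(back$timestamp), as.numeric(ser$timestamp))
  expect_equal(back$value, ser$value, tolerance = 1e-10)
  unlink(path)
})
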