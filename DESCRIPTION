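Package: rhythmdiff
Title: Differential Circadian Rhythmicity Analysis for Two-Group Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting and comparing circadian rhythms in gene
    expression time courses from two groups (e.g. fibroblasts entrained with
    serum from young versus old donors) and in wearable-device streams.
    Implements fixed-period single-component cosinor regression, a four-model
    weighted-BIC rhythmicity classifier, joint two-group cosinor fitting with
    Wald tests for differences in MESOR, amplitude and acrophase,
    Benjamini-Hochberg adjustment per statistic family, a two-sample Kuiper
    test with resampled p-values for circular phases, the exact Wilcoxon
    rank-sum test, gene-subset filters and heatmap normalization, and a
    synthetic-data generator with ground truth emulating a serum-entrainment
    experimental design so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
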