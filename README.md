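# rhythmdiff

Differential circadian rhythmicity analysis for two-group expression time
courses and wearable streams.

## What problem it solves

Peripheral circadian clocks in cultured cells can be entrained with human
serum and the transcriptome sampled over time. When cells are entrained with
serum from two donor groups — young versus old — each gene poses three
questions: is it rhythmic, and in which group(s)? For genes rhythmic in both,
do MESOR (rhythm-adjusted mean), amplitude, or acrophase (peak time) differ
between groups? And which gene sets defined by those calls should feed
enrichment tools? `rhythmdiff` answers all three for a design with several
serum donors per group and dense sampling (by default every 2 h, 32–58 h post
serum addition), on log10(1 + normalized count) values. The same cosinor
machinery serves wearable-device streams (actigraphy, heart rate), with
subjects in place of genes.

It is aimed at chronobiologists and genomics analysts who want a tested,
scriptable, dependency-light implementation of this analysis chain, including
a synthetic-data generator with ground truth so every stage runs offline.

## The statistics at its core

* **Cosinor regression** with fixed period T = 24 h:
  `y = M + A·cos(2π(t − φ)/T) + ε`, linearized and solved by OLS;
  rhythmicity via the 2-df F-test of the cosine/sine pair.
* **Four-model weighted-BIC classification**: per gene, Gaussian least-squares
  models for rhythmic-in-neither / young-only / old-only / both (shared
  residual variance each; BIC = k·ln n − 2·logLik), converted to Schwarz
  weights `w_i = exp(−ΔBIC_i/2)/Σ exp(−ΔBIC_j/2)`; class = the model with
  weight strictly > 0.75.
* **Joint differential fit** `y = (k + k₁G) + (α + α₁G)·cos(2π(t − φ − φ₁G)/T)`
  (G = old-group indicator), a reparameterization of the two per-group fits
  exploited for exact starts and verifiable convergence; Wald t-tests for
  k₁, α₁, φ₁ with φ₁ wrapped to (−12, 12] (positive = delayed in old);
  Benjamini–Hochberg per statistic family, with the phase family gated to
  genes rhythmic in both groups.
* **Nonparametric group tests**: exact two-sided Wilcoxon rank-sum for
  MESOR/amplitude; two-sample Kuiper test (rotation-invariant, V = D⁺ + D⁻)
  with seeded permutation p-values for circular acrophases.

See `vignettes/differential-rhythmicity.Rmd` for assumptions, conventions and
limitations.

## Worked example

```r
library(rhythmdiff)

sim    <- generate_expression_dataset(simulation_config(n_genes = 200, seed = 42))
report <- run_pipeline(sim$dataset)
table(truth = sim$truth$true_class, called = report$rhythm_class)
```

```
            called
truth        arrhythmic rhythmic_both rhythmic_old_only rhythmic_young_only unclassified
  both                0            50                 0                   0            0
  neither            48             0                 0                   1            1
  old_only            0             0                49                   0            1
  young_only          0             0                 0                  50            0
```

197/200 genes receive their true class at the weighted-BIC > 0.75 criterion.
A gene simulated with a +2 h phase shift in the old group is recovered with
the right sign, size and significance:

```r
g <- report[report$gene_id == sim$truth$gene_id[sim$truth$has_delta_phase][1], ]
#> gene gene_0004: dphi = 1.815 h (q = 1.7e-11), class = rhythmic_both

lengths(subset_filters(report))
#>  subset_decreased_mesor  subset_increased_mesor    subset_phase_advance
#>                       0                      13                       0
#>      subset_phase_delay subset_loss_rhythmicity subset_gain_rhythmicity
#>                      13                      51                      49
#>    subset_rhythmic_both
#>                      50
```

Only "increased MESOR" and "phase delay" subsets are populated — exactly the
effects the generator injects (ΔM = +0.5, Δφ = +2 h in old).

The wearables chain on a simulated cohort (7 young, 8 old subjects, old
acrophase 2 h earlier):

```r
ser <- generate_wearable_series(seed = 7)
analyze_wearables(ser, nboots = 1000, seed = 8)$comparisons
#>   parameter     test statistic      p median_young median_old
#> 1     mesor wilcoxon        74 0.0401         2000       2000
#> 2 amplitude wilcoxon        54 0.8665          999       1002
#> 3 acrophase   kuiper         1 0.0040           16         14
```

The designed 2 h phase advance is detected (Kuiper p = 0.004) while the
MESOR/amplitude estimates are essentially identical across groups — the
borderline MESOR rank-test p at this seed is a reminder that 3 tests × noise
will occasionally graze 0.05 under the null.

A command-line wrapper covers the same flow
(`inst/scripts/rhythmdiff simulate|fit|classify|wearables`), writing TSV
reports, subset gene lists and a heatmap matrix atomically and
byte-reproducibly.

## Analyzing the real dataset

The motivating experiment's sequencing data are deposited in GEO under
accession **GSE270290**. They are not required by anything in this
repository, but to analyze them: export normalized counts as
log10(1 + count) into the matrix TSV layout (`gene_id` + one column per
sample), write the annotation TSV (`sample_id`, `group` = young/old,
`donor` = A–D, `timepoint_hr` = 32–58), and run
`run_pipeline(load_expression("matrix.tsv", "annotation.tsv"))` or the
`classify` subcommand.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch at
a given seed — simulating the expression design, running the full per-gene
pipeline and subset filters, and running the wearable chain — and writes its
JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
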