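---
title: "Detecting differential circadian rhythmicity with rhythmdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential circadian rhythmicity with rhythmdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmdiff)
```

## The scientific problem

Peripheral circadian clocks — for instance in cultured fibroblasts — can be
synchronized ("entrained") by human serum, and the entrained transcriptome can
then be sampled over time to ask which genes oscillate with a ~24 h period.
When the same cells are entrained with serum from two donor groups (young
versus old), three questions arise per gene:

1. **Is the gene rhythmic at all, and in which group(s)?**
2. **Among genes rhythmic in both groups, do the rhythm parameters — MESOR
   (rhythm-adjusted mean), amplitude, acrophase (peak time) — differ between
   groups?**
3. **Which gene sets defined by these calls should go into downstream
   enrichment analyses?**

`rhythmdiff` implements this analysis chain for a design with two groups,
several serum donors per group, and a dense sampling grid (by default every
2 h from 32 to 58 h after serum addition, i.e. 14 timepoints × 4 donors ×
2 groups = 112 samples), operating on log10(1 + normalized count) expression
values. The same cosinor machinery is reused for wearable-device streams
(actigraphy counts, heart rate), where subjects rather than genes are the unit
of analysis.

## The cosinor model

All rhythm estimation is single-component cosinor regression with a *fixed*
period $T$ (24 h throughout; period estimation is out of scope):

$$ y(t) = M + A\cos\!\left(\tfrac{2\pi}{T}(t - \phi)\right) + \varepsilon $$

which is linear in $\beta_0 = M$, $\beta_1 = A\cos(2\pi\phi/T)$ and
$\beta_2 = A\sin(2\pi\phi/T)$, so `fit_cosinor()` solves it by ordinary least
squares and reports $A = \sqrt{\beta_1^2+\beta_2^2}$ and
$\phi = \tfrac{T}{2\pi}\,\mathrm{atan2}(\beta_2, \beta_1) \bmod T$.

**Conventions and edge cases.**

* The acrophase is the clock time of the fitted *peak*, in $[0, T)$; the sign
  convention is fixed by writing the model as above (a pure cosine peaking at
  $t_0$ yields $\phi = t_0 \bmod T$).
* If the fitted amplitude is at rounding-noise level the acrophase is
  undefined; it is reported as 0 with `phase_defined = FALSE`.
* Rhythmicity per series is the 2-df F-test of $\beta_1=\beta_2=0$; an exactly
  constant series returns $F = 0$, $p = 1$.
* The residual variance is stored as the MLE $\mathrm{rss}/n$ because the BIC
  computation below needs the maximized likelihood; the F-test uses the
  unbiased denominator $\mathrm{rss}/(n-3)$.
* Designs with fewer than 4 points, or with all times congruent modulo the
  period (a rank-deficient basis), are errors, not silent degenerate fits.

## Four-model rhythmicity classification

Following the weighted-BIC idea used for two-condition rhythmicity screens,
`fit_four_models()` fits, by pooled least squares with group-specific
intercepts, four Gaussian models per gene: rhythmic in **neither** group
(2 regression parameters), in the **young group only** (4), the **old group
only** (4), or **both** groups with independent rhythms (6). Each model has a
single shared residual variance (counted as one extra parameter), so
$k \in \{3, 5, 5, 7\}$ and

$$ \mathrm{BIC}_i = k_i \ln n - 2\hat\ell_i, \qquad
   w_i = \frac{e^{-\Delta_i/2}}{\sum_j e^{-\Delta_j/2}},
   \quad \Delta_i = \mathrm{BIC}_i - \min_j \mathrm{BIC}_j. $$

$n$ is the total observation count across both groups (112 in the default
design). The Schwarz weights $w_i$ sum to one and act as approximate posterior
model probabilities; `classify_rhythmicity()` assigns the class whose weight
*strictly* exceeds 0.75 (a threshold at or below 0.5 would allow two winners
and is rejected). A fifth "same rhythm in both groups" model is deliberately
not included: the classification is defined over exactly these four
hypotheses.

Numerical notes: weights are computed after subtracting the minimum BIC, so
huge BIC gaps cannot overflow; an exactly zero residual variance (possible
only for noise-free synthetic input) is floored at the smallest positive
double so that the most parsimonious perfectly fitting model wins
deterministically.

## Joint differential fit

For parameter differences the two groups are fit *jointly*
(`fit_joint_cosinor()`) with the group indicator $G$ entering every
parameter:

$$ y = (k + k_1 G) + (\alpha + \alpha_1 G)
   \cos\!\left(\tfrac{2\pi}{T}(t - \phi - \phi_1 G)\right) + \varepsilon, $$

so $k_1$, $\alpha_1$, $\phi_1$ are directly the MESOR, amplitude and phase
differences (old − young). This model is an exact reparameterization of two
independent per-group cosinor fits, which the implementation exploits twice:

* the optimizer (a small Levenberg-style Gauss–Newton loop) starts at the
  closed-form solution assembled from the two linear fits, so it converges
  immediately in regular cases; and
* the attainable minimum of the residual sum of squares is *known* (the sum of
  the two per-group RSS), so non-convergence is detectable and such genes are
  flagged (`converged = FALSE`, missing p-values) rather than silently
  reported.

Standard errors come from the Jacobian at the solution
($\widehat{\mathrm{cov}} = \hat\sigma^2 (J^\top J)^{-1}$,
$\hat\sigma^2 = \mathrm{rss}/(n-6)$) and p-values are two-sided t-tests with
$n-6$ degrees of freedom — the standard asymptotics of nonlinear least
squares. Phase differences are wrapped to the signed half-period
$(-T/2, T/2]$ (`wrap_phase_difference()`), where positive means the old group
peaks *later* (a delay); the boundary $T/2$ maps to $+T/2$. With noise-free
input the residual variance can be exactly zero; the Wald test then returns
$p = 1$ when the estimate is also zero and $p = 0$ otherwise, so constructed
identical-group examples behave as expected.

Per-group rhythmicity p-values are the per-group cosinor F-tests (the
amplitude Wald test is an alternative, but the F-test is the standard
zero-amplitude cosinor test and is what the per-group `p_rhythm_*` columns
report).

## Multiple testing and gating

`bh_adjust()` applies Benjamini–Hochberg *separately per statistic family*
across genes: per-group rhythmicity (young, old) and MESOR/amplitude
differences each form a family over all analyzed genes. Phase is different:
a phase difference is only interpretable for genes rhythmic in both groups,
so the phase-difference BH family is restricted to a *gate*. The gate is a
configuration switch (`pipeline_config(phase_gate = )`):

* `"bic"` (default): the weighted-BIC class `rhythmic_both`
  ($w_{both} > 0.75$), matching how the headline phase counts are defined;
* `"circa"`: per-group rhythmicity q-values both below the cutoff, matching
  how the enrichment gene subsets are defined.

Both gates are computed on every run; only the BH family membership switches.
Missing p-values (failed fits, gated-out genes) are propagated as `NA` and do
**not** count toward the family size — base R's `p.adjust` would count them,
which is why the wrapper exists.

## Gene subsets and log2 fold-change screens

`subset_filters()` implements seven published-style conjunctions as pure
functions of the report columns (so they can be re-derived and checked):
decreased/increased MESOR (per-group rhythm q < 0.05 in both groups, MESOR
difference q < 0.05, sign of the difference), phase advance/delay (same with
the phase q-value), and loss/gain/shared rhythmicity (the young-only,
old-only, both model weights > 0.75). All threshold comparisons are strict.

The volcano-style screens (`log2fc_screens()`) additionally require
$|\log_2 \mathrm{FC}|$ above a strict threshold (0.25 for MESOR, 0.1 for
amplitude). Because the data are log10(1+count), no fold change is defined by
the source material; the package's convention is

* `log2fc_mesor` $= (M_{old} - M_{young}) / \log_{10} 2$ — the MESOR
  difference re-expressed in log2 units of (1 + count);
* `log2fc_amplitude` $= \log_2 (A_{old} / A_{young})$ — the amplitude ratio.

This is a documented convention, not an attribution; it is the natural
re-scaling on each quantity's own scale (MESORs are log-abundances, so their
difference is already a log fold change; amplitudes are positive magnitudes,
so their ratio is).

## Heatmap normalization

`heatmap_normalize()` applies, per gene, the three display-only rounds:
(1) mean-center within each group × serum donor (removing baseline
differences between sera); (2) average replicates per group × timepoint;
(3) Z-score across timepoints within each group, using the *sample* standard
deviation (a fixed, asserted choice). A gene constant within a group would
divide by zero; it is emitted as an all-zero row with `constant = TRUE`
rather than `NaN`. These values feed plotting only, never the statistics.

## Nonparametric group tests

For subject-level comparisons of wearable-derived cosinor parameters:

* **MESOR, amplitude** — `wilcoxon_exact()`, the exact two-sided rank-sum
  test. The null distribution of $W$ comes from the standard counting
  recursion (`stats::pwilcox`); ties trigger a flagged midrank normal
  approximation with tie and continuity corrections (on continuous cosinor
  estimates ties have measure zero). If every pooled value is tied the test
  is uninformative and returns $p = 1$.
* **Acrophase** — `kuiper_two_sample()`, because phases are circular. The
  Kuiper statistic $V = D^+ + D^-$ is invariant under a common rotation of
  both samples (verified exactly in the tests), unlike Kolmogorov–Smirnov.
  The p-value is resampled: by default random reassignment of the pooled
  values to groups of the original sizes *without* replacement (a permutation
  test), with a with-replacement bootstrap behind `method = "bootstrap"` —
  the resampling scheme of the original tooling is not recoverable, so the
  conservative, exchangeability-exact permutation is the default. The
  add-one estimator $p = (1 + \#\{V^* \ge V\})/(1 + B)$ avoids $p = 0$, and
  a seed is part of the interface so every p-value is reproducible.

The wearable chain (`analyze_wearables()`) aggregates sub-minute activity
counts by summation into calendar minutes (rates such as heart rate use the
mean instead — summing bpm is meaningless), leaves empty minutes absent
rather than zero-filling, converts timestamps to hours since midnight of each
subject's first day, fits the fixed-24-h cosinor per subject, and routes the
three parameters to the two tests above. Gap handling is omission, not
imputation.

## The synthetic world

`generate_expression_dataset()` simulates the stated design: 2 groups × 4
donors × 14 timepoints (32–58 h, every 2 h), values
$M_g + A_g\cos(2\pi(t-\phi_g)/24) + \text{donor offset} + N(0, \sigma)$ on
the log scale. Defaults, chosen once:

| knob | default | rationale |
|---|---|---|
| class fractions | 0.25 each | covers all four classes symmetrically |
| `mesor_range` | 1–4 | typical log10(1+count) abundances |
| `amplitude_range` | 0.5–1.5 | clearly oscillating but not caricatural |
| `noise_sd` | 0.2 | amplitude/noise ≈ 2.5–7.5, a well-powered experiment |
| `donor_offset_sd` | 0.1 | modest between-serum baseline shifts |
| `delta_mesor` / `delta_amplitude` / `delta_phase_hours` | +0.5 / −0.3 / +2 | effect sizes detectable at this n |

Class counts are deterministic (`floor(frac × n)`, remainder to `neither`);
within the both-rhythmic block, genes cyclically receive no effect, a MESOR
shift, an amplitude change, or a phase delay, so ground truth enumerates
every differential scenario without extra randomness. All draws happen in one
documented order under one seed, so regeneration is bit-identical.

What the generator does **not** emulate: count-level sequencing noise
(everything is Gaussian on the log scale, because that is the scale the
inference consumes), library-size or normalization artifacts, correlated
gene modules, or donor-by-gene interactions. A green test on this world
therefore establishes correctness of the estimators and calibration under
the model's own assumptions — not robustness to real RNA-seq pathologies.
Similarly, `generate_wearable_series()` produces clean truncated-cosine
streams; real nonwear gaps, beat-correction artifacts and activity
burstiness are out of scope. Note also that the difference tests treat the
112 samples as independent: with a nonzero `donor_offset_sd` the within-donor
correlation makes the Wald tests slightly conservative/anticonservative
depending on the contrast, which is why the null-calibration checks use a
world with `donor_offset_sd = 0` — the pipeline models sera as exchangeable
replicates, not as random effects.

## Running on real data

The package is written so the deposited dataset of the motivating experiment
(GEO accession **GSE270290**) can be analyzed when a user downloads it: export
the normalized counts as `log10(1 + count)` to the matrix TSV layout
(`gene_id` column plus one column per sample) and an annotation TSV
(`sample_id`, `group` ∈ young/old, `donor` A–D, `timepoint_hr` 32–58), then
run `rhythmdiff classify --matrix ... --annotation ...` or
`run_pipeline(load_expression(...))`. Nothing in the test suite or CI
downloads data; this path is documentation only.

## Known limitations

* Fixed 24 h period only; no period scans or multi-harmonic fits.
* No mixed-effects donor modeling (replicates are treated as independent).
* Wald phase tests degrade when a group's amplitude approaches zero; such
  genes should be (and by the gate, are) excluded from phase inference.
* The exact Wilcoxon path requires both samples ≤ 25 without ties; beyond
  that the flagged normal approximation is used.
* The luciferase-reporter arm of the motivating experiment (period-in-range
  20–28 h exclusion of non-cycling replicates) concerns an external analysis
  service and is documented here only; no luminometer parser is provided.
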