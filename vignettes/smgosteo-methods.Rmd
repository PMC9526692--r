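---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smgosteo)
```

This vignette is the package's own account of the statistics it implements:
what each model assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic-data generators emulate (and
deliberately do not), and where a genuinely open design choice was settled.

## 1. The experimental design

Bone marrow stromal cells differentiate toward osteoblasts for 28 days
either on a random positioning machine (RPM, simulated microgravity) or in
a static gravity control (GC). Proteomes are sampled at T0 (start), day 8
and day 28. The resulting five classes carry three biological replicates
each, except `T8_GC` with two — 14 samples in total. After T0 ratioing the
differential analysis compares the four classes `T8_GC`, `T8_RPM`,
`T28_GC`, `T28_RPM` in a single one-way layout: time and gravity are fused
into one factor, which trades interaction modelling for robustness at
n = 2–3 per cell and matches how such data are commonly processed in
Perseus-style workflows.

## 2. Proteomics differential abundance

### Preprocessing

1. **T0 reference**: per-gene arithmetic mean of the non-missing T0
   replicates (`average_reference()`).
2. **Ratio**: each non-T0 intensity is divided by the reference; T0 columns
   are then dropped. A missing, zero or negative reference makes the whole
   gene missing (with a warning) rather than erroring — degenerate
   references can arise in synthetic edge cases and are cleaned up by the
   next step.
3. **Valid-value filter**: keep a gene iff some class has ≥ 70 % non-missing
   replicates. The fraction uses the exact class size with no rounding:
   2/3 = 0.667 fails, 2/2 passes. This is the step that makes downstream
   imputation defensible — every retained gene is genuinely observed in at
   least one class.
4. **log2 transform.**
5. **Imputation**: missing log2 values are drawn from
   `N(μ_s − downshift·σ_s, (width·σ_s)²)` where `μ_s`, `σ_s` are the sample
   column's observed mean and sd. Defaults `width = 0.3`,
   `downshift = 1.8` are the de-facto standard for label-free proteomics
   left-censoring imputation; both are exposed in `pipeline_config()`. The
   model assumes missingness is dominated by low-abundance dropout (MNAR);
   the generator (section 5) censors by the same mechanism, which is what
   makes the imputation testable.

### Testing

Per gene, the classical between/within mean-square F across the four
classes, with p from `F(k−1, N−k)` (`row_anova()`, vectorized; validated
against textbook sums-of-squares oracles and `stats::aov` to ≥ 6
significant digits). A constant gene (zero between- and within-group
variance) is defined as F = 0, p = 1; zero within- with positive
between-variance gives p = 0.

**Permutation FDR.** The class labels of the 11 samples are shuffled
`n_perm = 250` times (class sizes preserved) and all gene p values are
recomputed per shuffle. The estimated FDR at a candidate cutoff `c` is

> (mean over permutations of #{p_perm ≤ c}) / max(1, #{p_obs ≤ c})

and the significance cutoff is the largest observed p whose estimate is
≤ 5 %. This mean-ratio estimator with no variance-moderation fudge factor
(s0 = 0) is the simplest faithful reading of a permutation-based FDR with
a stated number of repetitions; it was chosen over SAM-style variants
because nothing in the procedure description requires test-statistic
moderation, and it keeps the estimator exactly reconstructible. Under a
global null the realized false-discovery proportion is 0 in most runs and
1 occasionally (any discovery is false); its mean over 20 simulated null
experiments stays within Monte-Carlo tolerance of 5 % (checked by the test
suite and `scripts/acceptance.R`).

**Post hoc.** Tukey HSD via the studentized range (Tukey–Kramer for the
unequal `T8_GC` class) on each significant gene; each of the 6 pairs
records the higher class and significance at `alpha = 0.05`.

**Isoform reduction.** Records whose gene symbols differ only by a
trailing `-<digits>` isoform suffix are collapsed to the smallest-p
record. The original study did this manually; the suffix-plus-minimum-p
rule automates it deterministically (ties break by gene name, as do all
ordering ties in the package).

**Trend classification.** A gene is "down at T8" iff the (`T8_GC`,
`T8_RPM`) pair is significant with the RPM mean lower (likewise up, and at
T28). The eight categories are: down/up at T8 only, down/up at T28 only,
down/up at both, `mixed` (opposite directions at the two times — a bin the
published pie charts leave unstated, added so the categories stay
exhaustive), and `time_only` for significant genes with no RPM-vs-GC pair
— these are attributed to maturation over time. At least one of the
within-condition time contrasts (`T8_GC` vs `T28_GC`, `T8_RPM` vs
`T28_RPM`) is usually the driver; the rare gene where only a cross pair
(e.g. `T8_GC` vs `T28_RPM`) is significant is also binned `time_only`
rather than given a ninth category, keeping the partition property
(category counts always sum to the number of significant genes).

The per-gene `neg_log_p` column is `−log2(p)`, matching the convention of
the supplementary tables this output mirrors.

**Ranking, clustering, PCA.** `top_regulated()` ranks genes by the mean
RPM − GC log2 difference averaged over the two time points.
`zscore_and_cluster()` z-scores rows and clusters rows and columns with
average-linkage/Euclidean `hclust` (deterministic leaf order).
`pca_variance()` runs PCA with samples as observations on the mean-centered
log2 ratio matrix; fractions sum to 1. PCA is deliberately computed on the
pipeline's own log2 ratio matrix rather than a count-model variance
stabilizing transform: VST is designed for sequencing counts and its use
on proteomics intensities is non-standard, while the log2 ratio matrix is
exactly what every other step of this pipeline consumes.

## 3. Concentric radial belts

The geometric question the algorithm answers: *how is fluorescence
distributed from the centrosome to the cell edge, when the cell is not a
circle?* The answer is per-ray normalization. For pixel `p`, centrosome
`c` and the drawn polygon:

* `ρ(p) = |p − c| / R(θ)`, where `R(θ)` is the distance from `c` to the
  *first* polygon-boundary intersection along the ray through `p`;
* belt index `b = min(⌊ρ · n_belts⌋, n_belts − 1)`, default
  `n_belts = 11` (belts 0–10, matching the published axis).

Belts are therefore equal in radial *fraction*, not in area — the
interpretation that matches "equally distributed belts from the center to
the cell edge" and the annular appearance of the published masks; an
equal-area reading would concentrate the outer belts into thin shells and
was rejected.

Numerical conventions: pixel `[i, j]` has center `(i, j)`; a pixel is
interior iff its center is inside the polygon by the even-odd rule;
ray–segment intersections are solved in continuous coordinates with an
endpoint tolerance of 1e−9 so rays through a vertex are not lost; the
centrosome is the maximum-intensity interior pixel with ties broken by
smallest row then column. The per-pixel labels are checked against an
independent scalar oracle (per-segment 2×2 linear solves) for 100 % of
interior pixels, and against analytic annuli for a centered circular cell
(≥ 99 % agreement at 128×128; the residual is rasterization of the
polygonal approximation to the circle).

Area fractions use an Otsu threshold computed once per cell on interior
pixels (256-bin histogram; a constant interior thresholds at half its
value so a uniformly positive cell counts as fully stained). Otsu per cell
— rather than one global threshold per experiment — was chosen because
staining intensity varies cell to cell and the published procedure states
no threshold; a fixed numeric threshold can be passed instead
(`threshold =` in `belt_statistics()`), which is what one would use to
compare absolute staining across groups. Group comparisons
(`aggregate_cells()`) test each belt's mean intensity and area fraction
with the pooled-variance Student's t at 0.05.

## 4. Assay calculators

* `2^−ΔΔCt` (`ddct_fold_change()`): ΔCt = mean target Ct − mean reference
  Ct per condition; ΔΔCt subtracts the calibrator condition (GC). The sd
  is that of replicate-wise ΔCt values, propagated as the range
  `2^−(ΔΔCt ± sd)` — the common practice when no propagation rule is
  stated.
* Standard curves are strictly linear OLS (both assays operate in their
  linear range); four-parameter logistic fits are deliberately out of
  scope. `fit_standard_curve()`/`calibrate()` are exact mutual inverses on
  noiseless data; back-calculations outside the standard range are flagged
  `extrapolated`.
* The shared two-sample test is the pooled-variance Student's t (the test
  named throughout the study), with Welch available via
  `var_equal = FALSE`. Zero-pooled-variance cases are defined explicitly
  (equal means → p = 1; unequal → p = 0, flagged degenerate).
* `ora()`: hypergeometric upper tail with enrichment ratio
  `(k/n)/(K/N)`; no multiple-testing correction by default, matching a raw
  p < 0.05 reading, with Benjamini–Hochberg behind `adjust = TRUE`. The
  default background is the quantified matrix's own gene set — the most
  defensible universe when the true annotation background is unstated.

## 5. What the synthetic generators emulate — and what they do not

`simulate_proteomics()` draws per-protein baselines `log2 ~ N(20, 2²)`
(typical LFQ intensity scale), adds per-class spiked effects to a fraction
of proteins, replicate noise `N(0, 0.25²)`, and censors each sample's
linear intensities below that sample's empirical `mnar_quantile`
(default 5 %, a realistic DIA dropout rate). Spike trends are drawn
uniformly from the six SMG categories and their ground-truth labels use
the same sign mapping as `classify_trend`, so recovery is well-posed.
Defaults mirror the study conditions (replicate design 3/2/3/3/3; spike
checks use 10 % spiked at |effect| = 2 with noise 0.25).

Deliberately **not** emulated: correlated proteins (co-regulation),
heteroscedastic intensity-dependent noise, batch effects, peptide-level
inference, or informative missingness beyond the threshold mechanism.
Passing the recovery tests therefore demonstrates correctness of the
statistical machinery under its own model, not robustness to every
pathology of real data; on real matrices the permutation FDR inherits
whatever exchangeability the class labels actually have.

`simulate_cell_image()` builds intensity
`peak · exp(−decay · ρ) + noise` inside the polygon — a closed form whose
belt profile is known exactly, giving the decay-recovery check
(log-linear fit of belt means recovers `decay_rate` within 10 % at zero
noise; in practice within ~2 %, the residual being within-belt averaging
of a convex function). With noise, the designated centrosome pixel is
raised above the interior maximum so the ground-truth location stays
identifiable. Multi-channel images, z-stacks and automated segmentation
are out of scope (the cell edge is an input, as it was drawn manually in
the source workflow).

`simulate_ct_table()` and `simulate_plate()` invert the calculators they
feed exactly at zero noise (one PCR cycle = one doubling; absorbance
linear in concentration), each with triplicate wells/reads.

## 6. Problem sizes and determinism

The test suite and acceptance script run simulations at 150–1000 proteins
with the full 250-permutation FDR, 20 null replicates for the FDR-control
check, and 64×64 / 128×128 images — sizes chosen so the whole suite
completes in well under a minute while keeping every Monte-Carlo check
comfortably powered. Every stochastic step takes an explicit seed
(`withr::with_seed`, so the caller's RNG state is never disturbed), and the
pipeline's two stochastic stages (imputation, permutations) derive their
seeds from the single `pipeline_config()` seed; identical configurations
are bit-identical end to end.

## 7. Known limitations

* The one-way fusion of time × gravity cannot attribute a `time_only`
  gene to GC- versus RPM-driven maturation; that distinction needs the
  two-factor model this design is underpowered for.
* The permutation FDR estimates a global cutoff, not per-gene q values.
  With 250 permutations its resolution is limited near very small p
  values; raising `n_perm` is the remedy when compute allows.
* Isoform de-duplication trusts the `-<digits>` suffix convention of
  official gene symbols; unconventional isoform labels will not collapse.
* The belt algorithm assumes a simple (non-self-intersecting) polygon and
  a centrosome strictly inside it; strongly non-convex cells are handled
  per-ray (first boundary hit), which matches the "distance to the edge
  you can see" reading but will compress belts along rays that exit
  through a concavity.
* `2^−ΔΔCt` assumes perfect (100 %) amplification efficiency for both
  target and reference, as the method itself does.
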