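# smgosteo

Downstream analysis toolkit for osteogenic-differentiation experiments under
simulated microgravity (SMG). Human bone marrow stromal cells (BMSCs)
differentiated toward osteoblasts are compared between a random positioning
machine (RPM, simulating weightlessness) and a gravity control (GC) at two
time points (8 and 28 days, plus a T0 baseline). The package re-implements,
as tested and reusable R functions, the statistics such a study needs
downstream of instrument software:

* **Label-free DIA proteomics differential abundance.** Protein-group
  intensities are ratioed to the averaged T0 reference, filtered for ≥ 70 %
  valid values in at least one class, log2 transformed, and missing values —
  treated as left-censored, missing-not-at-random dropout — are imputed from
  a downshifted Gaussian `N(μ_s − 1.8·σ_s, (0.3·σ_s)²)` per sample column.
  Each protein group is tested with a one-way ANOVA across the four
  time × gravity classes (`T8_GC`, `T8_RPM`, `T28_GC`, `T28_RPM`), and
  significance is controlled by a **permutation-based FDR**: class labels
  are shuffled 250 times, and the cutoff `c*` is the largest observed p value
  with estimated FDR `E[#{p_perm ≤ c}] / #{p_obs ≤ c} ≤ 0.05`. Significant
  protein groups get Tukey HSD (Tukey–Kramer, unequal n) pair calls, isoform
  de-duplication, and a trend category — down/up-regulated in SMG at T8
  only, T28 only, both, `time_only` or `mixed`.
* **Concentric radial-belt image quantification.** For a fluorescence image
  of the microtubule network with a manually drawn cell-edge polygon, the
  centrosome is the brightest interior pixel, each pixel gets a normalized
  radius `ρ = |p − c| / R(θ)` (distance to the cell edge along the same
  ray), and the interior is partitioned into 11 belts
  `b = min(⌊ρ·11⌋, 10)` from centrosome (belt 0) to periphery (belt 10).
  Per belt: mean intensity and Otsu-thresholded area fraction; groups of
  cells are compared belt-wise with Student's t.
* **Assay calculators.** Relative qPCR expression by `2^−ΔΔCt` with an 18S
  rRNA reference, linear standard-curve calibration and back-calculation for
  enzymatic/ELISA plates, crystal-size summaries with shared-bin frequency
  distributions, and the shared pooled-variance Student's t test.
* **Over-representation analysis.** Hypergeometric upper-tail `P(X ≥ k)`
  of gene lists against user-supplied (GMT) annotation sets with enrichment
  ratio `(k/n)/(K/N)` — hermetic, no web services.
* **Synthetic data with known ground truth** for all of the above,
  including the study's replicate design (3 replicates per class, 2 for
  `T8_GC`) and per-sample quantile censoring for MNAR missingness — so every
  stage is testable without any external download.

## Worked example

```r
library(smgosteo)

sim <- simulate_proteomics(proteomics_sim_spec(500, frac_dapg = 0.1,
                                               effect_log2 = 2, seed = 42))
sim$matrix
#> intensity_matrix: 500 protein groups x 14 samples (linear scale)
#>   classes: T0(3) T8_GC(2) T8_RPM(3) T28_GC(3) T28_RPM(3)
#>   missing: 350 (5.0%), imputed: 0

res <- run_dapg_pipeline(sim$matrix, pipeline_config(seed = 42))
res$fdr$n_significant
#> [1] 45
res$summary
#>        category  n  pct
#> 1  down_T8_only  4  8.9
#> 2    up_T8_only 14 31.1
#> ...
```

45 of the 500 protein groups pass the 5 % permutation FDR (the true spiked
fraction is 10 %, i.e. 50 genes; sensitivity here is 0.84 at the modest
n = 500), and each is assigned the trend category of its Tukey pair calls.
The percentages are fractions of the significant, isoform-reduced set —
the numbers that would populate a trend pie chart.

The belt algorithm on a synthetic cell with exponential radial decay:

```r
sq <- rbind(c(4, 4), c(4, 60), c(60, 60), c(60, 4))
img <- simulate_cell_image(image_sim_spec(64, sq, c(32, 32),
                                          decay_rate = 2, noise_sd = 0, seed = 1))
belt_statistics(img, generate_belts(img, 11))
#>    belt mean_intensity area_fraction n_pixels
#> 1     0       8927.419             1       25
#> 2     1       7438.021             1       96
#> ...
#> 11   10       1474.609             0      535
```

Mean intensity decreases monotonically from centrosome to periphery and a
log-linear fit of the belt means recovers the simulated decay constant
within 2 %.

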