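# proxratio

Spatial proximity analysis for imaging-based spatial transcriptomics
(Xenium-style cell maps): are IL6-expressing fibroblasts enriched within
paracrine distance of ARG1+ cells?

In fibrotic lung tissue, ARG1+ cells (predominantly neutrophils) are
hypothesized to receive a secreted IL-6 signal from adjacent fibroblasts.
Given per-cell centroid coordinates (μm) and a sparse cell-by-gene count
matrix, `proxratio` quantifies this with the **co-occurrence probability
ratio** at a radial distance *d*:

```
R(d) = P(exp | reference, within d) / P(exp, within d)
```

For every reference (ARG1+) cell, the fraction of all cells within distance
≤ *d* (an *inclusive interval*, center included) belonging to the tested
category is computed; the numerator averages this fraction over reference
cells and the denominator averages the same per-center fraction over
**every** cell in the sample. R(d) > 1 means the category is spatially
enriched near the reference cells. A legacy discrete-annulus variant is
included for comparison.

The package implements the full pipeline as composable functions:

| step | function | defaults |
|---|---|---|
| QC filtering | `qc_filter()` | ≥ 10 counts/cell, then genes in ≥ 5 cells |
| normalization | `normalize_log()` | per-cell total 10⁴, log(1+x) |
| categorization | `assign_categories()` | ARG1 / IL6 / COL1A1, CTHRC1; nonzero = positive |
| proximity statistic | `cooccurrence_ratio()`, `cooccurrence_profile()` | 25 μm, inclusive mode |
| exhaustive oracle | `brute_force_ratio()` | bitwise-identical reference path |
| uncertainty | `subsample_ci()` | 5 × 50% subsamples, min/max interval |
| cohort inference | `run_cohort_analysis()`, `paired_t_test()` | paired t across samples |
| synthetic data | `simulation_config()`, `simulate_cell_map()`, `simulate_cohort()` | ground-truth planted enrichment |

Cell maps are read and written in 10x-style MatrixMarket format
(`read_cell_map()` / `write_cell_map()`), and a thin command-line wrapper
with `simulate` / `preprocess` / `cooccur` / `cohort` subcommands ships at
`system.file("cli", "proxratio.R", package = "proxratio")`.

## Worked example

Simulate a nine-patient cohort with 60% of IL6+ fibroblasts planted within
25 μm of a reference cell (IL6− fibroblasts are spatially random), then run
the full analysis:

```r
library(proxratio)

cfg <- simulation_config(domain_width = 400, domain_height = 400,
                         n_reference = 100, n_fib = 1000, n_other = 900,
                         enrichment_radius = 25, seed = 1)
sims <- simulate_cohort(cfg, n_samples = 9, effect_b_minus_c = 0.6)
sims$sample_01$map
#> cell_map: 2020 cells x 18 genes
#>   x range: [0.208188, 399.729] um; y range: [0.101307, 399.694] um
#>   total counts: 51010; median counts/cell: 25

fit <- run_cohort_analysis(lapply(sims, `[[`, "map"), radii = 25, seed = 1)
fit
#> cohort proximity analysis: 9 samples, primary radius 25 um
#>   il6pos_fib ratio: mean 1.238 (range 1.21-1.284)
#>   il6neg_fib ratio: mean 0.8993 (range 0.8559-0.9848)
#> paired t test on 9 sample pairs
#>   mean difference (b - c): 0.338538
#>   t = 21.7684, df = 8, two-sided p = 2.09132e-08
```

The IL6+ fibroblast ratio sits above 1 in every sample (the planted
enrichment is recovered), the IL6− fibroblast ratio does not, and the
paired t test across the nine samples detects the difference. Each row of
`fit$results` also carries the 5 × 50% subsampling min/max interval for
that sample's ratio; `write_results()` serializes the table with the
paired-test footer at full precision.

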