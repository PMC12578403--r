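---
title: "Co-occurrence probability ratios for spatial proximity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence probability ratios for spatial proximity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxratio)
```

## The question the statistic answers

Imaging-based spatial transcriptomics (e.g. 10x Xenium) yields, per tissue
section, a table of cell centroids in micrometres and a sparse cell-by-gene
count matrix over a targeted panel. A recurring question is whether one cell
population is spatially enriched near another at a paracrine signaling
scale — here, whether IL6-expressing fibroblasts are over-represented
within 25 μm of ARG1+ cells (in fibrotic lung, predominantly neutrophils),
as one would expect if the ARG1+ cells are receiving a secreted IL-6
signal from their immediate neighbours.

`proxratio` implements the full analysis as a reusable pipeline:

1. **QC**: cells with fewer than 10 total counts are removed, then genes
   detected in fewer than 5 of the surviving cells.
2. **Normalization**: counts scaled per cell to a total of 10^4, then
   log(1 + x). Categorization deliberately uses *raw* counts; the transform
   preserves the zero/nonzero pattern, and the package tests assert this
   invariance.
3. **Categorization** by marker positivity (a count strictly above 0 by
   default): `reference` = ARG1+ (takes precedence); `il6pos_fib` = ARG1−,
   IL6+, and COL1A1+ or CTHRC1+; `il6neg_fib` = ARG1−, IL6−, and COL1A1+
   or CTHRC1+; everything else `other`.
4. **The co-occurrence probability ratio** at radius *d*:
   P(exp | reference) / P(exp), estimated as described below.
5. **Uncertainty**: 5 random 50% subsamples of the cells; the interval is
   the min and max of the 5 subsample ratios.
6. **Cohort inference**: per-patient ratios for IL6+ versus IL6−
   fibroblasts compared with a two-sided paired Student's t test.

## The estimator

For a center cell *c*, let the neighborhood N(c, d) be **all** QC-passing
cells within Euclidean distance ≤ *d* of *c* — the *inclusive interval*
convention, as opposed to the legacy discrete-annulus binning which is
also provided (`mode = "annulus"`, half-open bins (r<sub>k−1</sub>,
r<sub>k</sub>], empty annuli dropped from the averages). The fraction of
N(c, d) belonging to the category of interest is computed per center;
the numerator averages this fraction over the reference cells and the
denominator averages the *same* fraction over every cell in the sample:

$$\widehat{R}(d) \;=\; \frac{\frac{1}{|A|}\sum_{c \in A} \frac{|N(c,d)\cap E|}{|N(c,d)|}}{\frac{1}{n}\sum_{c=1}^{n} \frac{|N(c,d)\cap E|}{|N(c,d)|}}$$

with *A* the reference cells and *E* the category being tested. Values
above 1 indicate enrichment near the reference cells. Averaging fractions
(not pooling counts) weights every reference cell equally regardless of
its local density.

Three conventions are fixed and exposed as options:

* the center cell counts in its own neighborhood (`include_center = TRUE`),
  which makes the full-coverage identity exact: when *d* exceeds the domain
  diameter every fraction equals the category frequency and the ratio is
  exactly 1;
* distance ties at exactly *d* are included (closed ball; `strict = FALSE`);
* neighborhood totals count all QC-passing cells, including `other` and
  reference cells.

Two implementations exist deliberately. The production path counts
neighbors with a uniform bucket grid in C++ (bucket side max(radius,
extent/256), 3×3 bucket sweep); the squared-distance inclusion predicate is
written identically in the pure-R exhaustive oracle (`brute_force_ratio`,
full pairwise distance matrix, no shared code), and the test suite asserts
bitwise-equal numerators, denominators and ratios on hundreds of random
instances. Because both paths reduce to integer neighbor counts, the
per-center fractions are identical rationals and the agreement is exact,
not approximate.

## Small-neighborhood bias of the null, and how checks are calibrated

Self-inclusion has one quantifiable cost. Under complete spatial
randomness (labels independent of positions), the every-cell denominator
is exactly unbiased for the category frequency, but a reference center is
a guaranteed non-member of the tested category inside its own ball, so the
numerator is shrunk by the factor B/(B+1) for neighborhood size B ≈
expected cells per ball. The null mean of the ratio is therefore not 1 but
approximately 1 − E[1/(B+1)], averaged over reference positions (edge
clipping makes border balls smaller and contributes most of the residual).
At B ≈ 5 this is a visible −15%; at B ≥ 150 it is a few tenths of a
percent.

All null-calibration checks in the package are therefore run at radii
where the predicted bias is small relative to the Monte-Carlo resolution
of the check, and the choice was made from this bias/variance analysis
(larger is not automatically better: numerator and denominator
fluctuations become correlated as balls approach full coverage, so the
ratio's noise collapses faster than its residual bias). Concretely, the
5000-cell CSR calibration uses a 150 μm radius (~350 expected neighbors),
and the permutation-null and generator-null property tests use radii with
150–400 expected neighbors. At the paper-scale 25 μm radius the bias
cancels in *comparisons* between categories measured on the same sample,
which is what the cohort test consumes.

## The synthetic-data generator

`simulate_cell_map()` emulates a Xenium-style sample as a marked point
process with known ground truth:

* reference cells, IL6− fibroblasts and `other` cells are placed uniformly
  in a rectangular domain (defaults 1000 × 1000 μm, ~2000 cells, matching
  the 10^3–10^4 cells of a desk-scale section);
* a fraction `enrichment_frac` of IL6+ fibroblasts is planted: each picks
  a uniform reference parent and a uniform offset in the disk of
  `enrichment_radius` (default 25 μm), rejection-sampled to stay in the
  domain. The uniform-disk offset (rather than a Gaussian) makes "all
  planted cells lie within the radius of their parent" an exactly testable
  geometric invariant;
* counts are negative binomial per (gene, cell type) mean with one
  dispersion (default 0.5, variance μ + 0.5μ²; 0 gives Poisson),
  independent genes. Marker genes of an expressing type are zero-truncated
  and then hit by Bernoulli dropout (default 0.1), so marker positivity
  equals the ground-truth type except where dropout struck, and never
  upgrades a cell (a cell cannot gain an identity it does not have);
* background genes (default 10 at mean 2) give realistic depth; regular
  cells are topped up to ≥ 10 total counts on a background gene so that
  exactly the configured `n_qc_fail_cells` (forced totals of 3–9) sit
  below the depth filter, and `n_rare_genes` planted genes are detected in
  fewer than 5 cells;
* `simulate_cohort()` derives per-sample seeds from the base seed with the
  stated stable map `(seed · 48271 + index · 1009) mod (2³¹ − 1)`, and
  applies the enrichment only to IL6+ fibroblasts, so a single effect
  number controls the expected between-category difference (0 = null
  cohort).

What the generator does **not** emulate: transcript-level spatial noise,
segmentation errors, cell shapes and sizes (cells are points), spatially
varying density, anisotropy, or correlated genes. Passing tests therefore
demonstrate correctness of the estimator and inference machinery under a
clean marked point process, not robustness to real-tissue artifacts.

## Numerical and procedural choices

* **QC order**: cells filtered first, then genes, in a single pass without
  iterating to a fixed point. A second application can in principle remove
  further cells (gene removal lowers totals); on realistic data rare genes
  carry too few counts for this to trigger, and the test suite checks
  idempotence on generator output.
* **Positivity** is evaluated on raw counts; the threshold (default:
  strictly more than 0 counts) is exposed (`category_rule(min_count = )`)
  for noisier panels.
* **Subsampling interval**: min/max of 5 ratios from 50% subsamples drawn
  uniformly without replacement over all cells jointly, reported verbatim
  as a range statistic — it carries no coverage guarantee and is not a
  calibrated confidence interval. Subsamples that lose every reference
  cell (or give an undefined 0/0 ratio) are redrawn, up to 100 attempts.
* **Degenerate cases**: a zero denominator yields an `undefined` flag, not
  an error; a sample with no reference cells errors; zero-variance
  differences in the paired test yield p = 1 (all-zero) or p = 0 with a
  `degenerate` flag (nonzero mean).
* **Coordinates** are taken as micrometres as exported by the platform; no
  pixel conversion. Results are exactly invariant under translation and
  joint scaling of coordinates and radius (tested as bitwise equality).
* **No edge correction** (no border or Ripley-style weighting): the
  every-cell denominator absorbs part of the edge effect, and the
  remainder is the documented small-neighborhood bias above.

## Problem sizes used by the test suite

The shipped checks run at desk scale by design: 5000-cell samples for the
CSR null calibration (20 replicates), a 750-cell planted-enrichment
recovery configuration (50 reference cells, 500 fibroblasts half IL6+,
60% of IL6+ fibroblasts clustered within 25 μm; pipeline mean over 25
replicates compared against a 400-replicate brute-force Monte-Carlo
reference frozen with its per-replicate SD), and a nine-sample cohort
emulation with 2000 cells per sample in a 400 × 400 μm domain (so a 25 μm
ball holds ~25 cells), 50 replicate cohorts for power and 200 for null
p-value uniformity. The cohort effect (80% of IL6+ fibroblasts planted)
is deliberately strong: the emulation checks that the machinery detects a
clear signal and stays calibrated under the null, not the power at any
particular biological effect size.

## Known limitations

* The min/max subsampling interval narrows as fewer subsamples are used
  and is sensitive to the subsample count; it is reproduced as specified,
  not recommended as a general-purpose interval.
* The paired t test assumes approximately normal per-sample ratio
  differences; with very few reference cells per sample the ratios are
  discrete and the test's calibration degrades.
* The estimator's small-neighborhood null bias (above) means single-sample
  ratios at sparse radii should not be read against an absolute threshold
  of 1; comparisons between categories on the same sample are the intended
  use.
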