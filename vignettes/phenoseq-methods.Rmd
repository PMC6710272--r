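---
title: "Models and methods behind phenoseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenoseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoseq)
```

## The problem

Clonal spheroids grown from single cancer cells differ visibly — round
epithelial structures versus invasive, aberrant shapes; small versus large
spheres — and those morphologies track transcriptional programs.
Profiling an *intact* spheroid yields one image and one RNA-seq library
per structure, but the library pools an unknown-but-estimable number of
cells `n_i`. This package implements the computational chain that turns
such data into (i) per-spheroid morphology features, (ii) a
cell-number-normalized count matrix, (iii) inferred single-cell regulatory
states per gene, and (iv) lineage-signature scores per spheroid.

## The LN-LN mixed-n model

Each cell expresses a gene at a low level `LN(mu1, sigma)` or, with
probability `F`, at a high level `LN(mu2, sigma)`; the two states share
the log-SD `sigma`. For lognormals the coefficient of variation depends
only on `sigma`, so "common log-SD" and "common CV" are the same
constraint — we parameterize by `sigma`. A spheroid's measurement is
assumed to scale linearly with its cell number: `y_i` is the sum of `n_i`
independent per-cell draws. Marginalizing the binomial number `h` of
high-state cells:

$$p(y_i \mid n_i) = \sum_{h=0}^{n_i} \binom{n_i}{h} F^h (1-F)^{n_i-h}
  \, LN\!\big(y_i; \mu_*(h), \sigma_*(h)\big)$$

**Sum approximation.** The distribution of a sum of lognormals has no
closed form. We use Fenton–Wilkinson moment matching: the sum of `c_j`
terms at log-mean `mu_j` (shared `sigma`) is approximated by the lognormal
with the same mean and variance. A Monte-Carlo oracle
(`mc_sum_density_oracle`, independent of the fitting code) bounds the
error: at the reference parameters (0, 2, F = 0.2, sigma = 0.5) the
sup-norm discrepancy is zero at n = 1 (FW is exact for a single cell),
~1% at n = 2, ~4% at n = 5 and ~7% at n = 10 — moment matching across
two populations ~7-fold apart in scale degrades slowly as pools grow.
`mixture_density(mode = "numeric")` provides the validation-grade
alternative: the exact n-fold FFT convolution of the single-cell mixture
density, accurate to well under 1% but too slow for per-gene
optimization, which therefore always uses FW. The Monte-Carlo oracle
estimates its kernel density on the log scale with a fixed 0.03-log-unit
bandwidth and back-transforms; automatic bandwidths oversmooth bimodal
log-densities, and a single linear-scale bandwidth cannot resolve the
narrow low-expression mode and the wide high-expression tail at once.

**Optimization.** The likelihood is multimodal, so `fit_gene` runs
multi-start (default 10) BFGS in transformed coordinates — unconstrained
log-means, `logit(F)`, `log(sigma)` — with starts drawn from quantiles of
`log(y_i / n_i)` plus seeded jitter. Identifiability: `mu1 <= mu2` is
enforced by relabeling after the fit (swapping also maps `F` to `1 - F`),
which keeps the objective smooth. Equal-likelihood starts (within 1e-8)
are resolved by the lexicographically smallest parameter vector. Log
densities are floored at `log(1e-300)` so the optimizer never sees `-Inf`;
parameter proposals outside a generous box (|mu| <= 100,
|log sigma| <= 10) are rejected with a large penalty.

**Model selection.** The one-population null (`k = 2`) and the
two-population model (`k = 4`) are compared by
`BIC = -2 logL + k ln(N)`, `N` = number of spheroids; the smaller BIC
wins. Selection power depends strongly on pool size: bimodality washes
out of a pooled measurement as `n_i` grows. At `Delta mu = 2`,
`sigma = 0.5`, `F = 0.2`, the mean log-likelihood advantage of the true
two-population model is only ~1.8 for pools of 5–50 cells — below the BIC
penalty difference `ln(200) ~ 5.3` — whereas for pools of 1–10 cells
(the regime the stochastic-profiling approach was designed around, and
what the acceptance suite simulates) detection is essentially perfect.
Parameter *recovery* when fitting the two-population model directly is
accurate even at 5–50 cells; it is the *null-versus-mixture decision*
that loses power with pool size. Fits on real data should therefore be
read jointly with estimated cell numbers.

## Normalization chain

1. **QC**: keep libraries with > 200,000 counts, > 3,000 detected genes
   and < 15% mitochondrial counts (defaults; all configurable).
   Mitochondrial genes are matched by an explicit list or the `MT-`
   prefix.
2. **Cell numbers**: a power law `count = a * area^b` fitted by log-log
   least squares to calibration pairs (spheroid pixel area vs nuclei
   count). The functional form is our choice — calibration data of this
   kind is well described by a power law, and the noiseless-recovery and
   10%-noise tests pin the estimator. Predictions are rounded and floored
   at 1 cell.
3. **Downsampling**: each column is reduced to exactly
   `target_per_cell * n_i` counts by a without-replacement (multivariate
   hypergeometric) subsample — not binomial thinning — so column totals
   correlate *exactly* 1 with cell numbers afterwards. A helper suggests
   the largest multiple of 100 below the minimal per-cell count, mirroring
   the choice of 2300 under a minimum of 2374.644; the target always
   remains an explicit user decision. Each column draws from a seed
   derived from `(seed, spheroid_id)` and genes are processed in sorted
   identifier order, so results are invariant to row and column order.
4. **Gene filters**: keep genes with mean count >= 1 in the *original*
   matrix and >= 5 counts in >= 2 wells of the *working* (downsampled)
   matrix. Which matrix the second rule reads is ambiguous in the source
   description; the downsampled matrix is the default and a
   `count_rule_on` switch exposes the alternative.
5. **Zeros** become 0.1 before lognormal fitting (`replace_zeros`).

## Image analysis

Two presets share one segmentation core:

* **Immunofluorescence**: average-intensity z-projection, Gaussian
  `sigma = 2`, Otsu threshold, 8-connected components, size filter
  300–800,000 px, per-object mean channel intensity.
* **RNA FISH**: maximum-intensity projection, Gaussian `sigma = 5` plus a
  grayscale maximum filter of radius 12 px, Otsu, keep only the biggest
  object; signal quantified as the fraction of object pixels above the
  intermodes threshold — the histogram is smoothed with a 3-bin mean
  filter until exactly two maxima `j < k` remain and the threshold is
  `(j + k) / 2`. A histogram that reaches unimodality instead raises an
  explicit bimodality error.

**Connectivity** is 8-connected (the common blob-detection default; the
source names only "connected component analysis").

**Perimeter/circularity.** Circularity is `4*pi*area / perimeter^2`,
capped at 1. The perimeter estimator is a marching-squares contour
(level 0.5 on the zero-padded mask) smoothed with a 3-vertex circular
moving average. The raw marching-squares polygon overestimates a digitized
circle's perimeter by ~5.5% (staircase bias), which would push disk
circularity down to ~0.90; the light smoothing removes the staircase
while barely shortening straight edges and corners. Measured on known
geometry before freezing: square side 100 scores 0.794 (ideal
polygonal value pi/4 = 0.785), disks r = 30/50/60 score 0.971/0.980/0.977,
and disk > 2:1 ellipse (0.82) > four-armed star (0.54). Absolute
circularity values are comparable across estimators only approximately;
orderings are robust.

**Well assignment.** Fields of view span a 2x2 block of nanowells
(512x512 px default); fields are cut into quadrants and well coordinates
derived from the scan position, with raster (default) or serpentine order
— the microscope's tiling order is configurable because it is not
universal.

## Signature scoring

Scores control for technical covariates with expression-matched random
gene sets: background (non-signature) genes are ranked by mean expression
and cut into 25 equal-size bins; each signature gene draws 100 controls
from the bin covering its own mean; the score is the signature-mean minus
control-mean expression per spheroid. Signature genes are excluded from
control pools — a coordinated program must not serve as its own
background (with 500 genes and 25 bins, a 20-gene program that shifts
coherently would otherwise fill its bin and cancel itself; the planted
+2 shift recovery test demonstrates exactly this failure mode).
Scoring operates on `log2(x + 1)` of the downsampled counts in the CLI;
the transform is the caller's choice at the function level. Bin and
control counts follow the established control-gene-set practice and are
exposed as parameters.

Cluster comparisons use the classic equal-variance unpaired two-tailed
Student's t-test, reported as `(t, df, p)`.

Anchor signatures take the top-20 Pearson correlates of a marker gene
(stem- or differentiation-anchored programs); zero-variance genes rank
last with undefined correlation, and ties break by gene identifier so
results are deterministic. The ribosomal/transit-amplifying program is a
user-supplied fixed list: the 24-gene list used in the original analysis
is not enumerated anywhere we can read, so no stand-in list is bundled as
if it were authoritative.

Pseudobulk reconstruction shuffles each class's cells into `n_groups`
near-equal groups (sizes differ by <= 1) per randomization and averages
counts — with 2 classes, 4 groups and 1 randomization this yields exactly
8 profiles.

Overlap enrichment is the upper-tail hypergeometric test of
`|set ∩ query|` against a fixed universe, BH-corrected across sets. It is
a pure overlap test by design; no ranked GSEA statistic is provided.

## What the synthetic data does and does not establish

The generators reproduce the statistical structure the pipeline assumes:
per-cell lognormal mixtures summed over heterogeneous known `n_i`,
multinomial count columns whose totals scale exactly with cell number,
disk/star/debris objects with exact pixel ground truth, and power-law
calibration pairs. They deliberately omit: read-level artifacts (PCR
duplication, barcode errors, mapping), gene-gene correlation within cells
(the model is fitted gene by gene), cell segmentation errors in the
images, and uncertainty in the cell-number estimates themselves (the
model treats `n_i` as known). A green test suite therefore establishes
correctness of the implementation under the model's assumptions — not
that real spheroid data satisfies those assumptions.

## Degenerate inputs and numerical choices

* `sigma -> 0` degenerates gracefully everywhere (point-mass limits).
* Constant images yield an empty mask plus a warning (Otsu undefined);
  constant expression vectors raise a degenerate-data error before
  fitting.
* Downsampling refuses targets above any column's total, naming the
  offending spheroid.
* All generators and fitters take explicit integer seeds; none touch
  global RNG state beyond their own `set.seed`, and per-column /
  per-gene seeds are derived from identifiers so execution order never
  matters.
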