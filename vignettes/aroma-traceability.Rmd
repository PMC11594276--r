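---
title: "Methods: volatile quantification, OAV profiling and producing-area discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volatile quantification, OAV profiling and producing-area discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromatrace)
```

This vignette documents the models, conventions and design choices behind
the package: what each stage computes, which parameters matter, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open.

## Quantification model

Volatiles are quantified against a spiked internal standard
(4-methyl-2-pentanol, 324.4 µg/L). A calibration line relates the
concentration ratio $x = c/c_\mathrm{istd}$ to the peak-area ratio
$y = A/A_\mathrm{istd}$:

$$ y = a\,x + b, \qquad c = \frac{y - b}{a}\, c_\mathrm{istd}. $$

Conventions, each of which was an open choice:

* **Curve orientation.** $x$ is the concentration ratio and $y$ the area
  ratio, so inversion divides by the slope. This matches standard practice
  for internal-standard curves; the alternative orientation would multiply.
  The choice is visible in the object fields and in `invert_calibration()`.
* **Unweighted OLS.** No $1/x$ weighting is applied; `fit_calibration()` is
  plain least squares with $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$.
* **Negative inversions clamp to zero** with a `below_range` flag rather
  than erroring: real baseline noise routinely produces small negative
  back-calculated concentrations.
* **Extrapolation is permitted but flagged** (`extrapolated`): samples do
  exceed calibrated ranges in practice and a hard error would be
  obstructive, but the flag keeps the information auditable.
* **Internal-standard scale.** Inverted values are multiplied by the
  internal-standard concentration so outputs are in µg/L rather than
  dimensionless ratios; the `internal_standard()` object records the scale.

Compounds without their own standard get a **surrogate curve**: the curve of
a compound of the same chemical class with minimal $|\Delta$ carbon
count$|$; ties go to the smaller carbon count, then the lexicographically
smaller CAS, so the assignment is a pure function. When no same-class curve
exists the caller must opt in to class relaxation explicitly — silently
quantifying an ester on an alcohol curve would be a scientific error, not a
convenience.

The packaged curve library (`calibration_library()`) carries the printed
$R^2$ values as metadata only: the raw calibration points behind them were
never published, so they cannot be re-derived and nothing asserts them.

**Retention indices** are linear temperature-programmed indices against an
n-alkane ladder, $RI = 100\,(n + (rt - rt_n)/(rt_{n+1} - rt_n))$; the index
is exactly $100n$ at each alkane and monotone in retention time. Peak
detection, modulation handling and spectral matching are out of scope
(vendor-software territory).

## Odor activity and aroma series

$\mathrm{OAV} = c/t$ with threshold $t$ taken from the compound catalog.
Thresholds in the catalog were determined in different matrices (water,
model wine, air — the `threshold_matrix` code); they are used as given, with
the matrix code carried as metadata only, because mixing literature
thresholds without matrix correction is exactly how such tables are built.
Zero (not-detected) concentrations give OAV 0.

The **activity filter** keeps compounds whose *maximum* OAV across groups
strictly exceeds the cutoff (default 1): a compound active anywhere is
retained for all groups, which is why activity tables legitimately contain
sub-1 and 0.00 cells. **Aroma series** are scored per group as the sum of
member OAVs; each compound belongs to exactly one series (the catalog has a
single type label per compound — multi-descriptor membership is not
modeled). The packaged catalog contains eight distinct series labels, and
the package treats the label set as data rather than fixing a count.

## Discrimination machinery

### Scaling

Chemical variables are normalized before modelling. Unit-variance scaling is
the default, Pareto ($\sqrt{sd}$) is available; the exact normalization used
by commercial chemometrics software is rarely reported, so both are exposed
and recorded in the fitted object. Constant columns cannot be scaled and are
dropped with a warning. Concentration panels are log-normal, so the
package's own analyses model **log concentrations**; the generator's effect
sizes are correspondingly defined on the natural-log scale.

### OPLS-DA

`opls_da()` one-hot encodes the class factor, centers it, and then:

1. **Orthogonal filter** (repeated `n_orth` times): one NIPALS component is
   fit, its X-loading is projected off the span of the Y-predictive weight
   space (the orthonormal basis of $X^\top Y$), and the resulting
   Y-orthogonal direction is removed from X.
2. **Predictive components** (`n_pred`, default one less than the number of
   classes): NIPALS PLS2 on the filtered matrix, deflating X and Y.

With `n_orth = 0` the model *is* plain PLS-DA; the test suite checks this
reduction against an independently coded reference PLS and against
mixOmics. Predictive and orthogonal score blocks are mutually orthogonal by
construction, and X-variance bookkeeping closes:
$R^2X_\mathrm{pred} + R^2X_\mathrm{orth} + \mathrm{residual} = 1$.

**NIPALS convergence.** The iteration converges on the score vector
(relative tolerance $10^{-9}$, 200 iterations). Power iteration stalls
exactly when the two leading eigendirections of $X^\top Y Y^\top X$ are
near-tied — routine under permuted labels, where any direction in the tied
subspace is an equally valid component. A stalled iteration is therefore
finished with the exact fixed point, the leading left singular vector of
$X^\top Y$, rather than raising an error that would abort permutation tests
precisely on the null datasets they exist to probe. Degenerate inputs
(vanishing $X^\top u$ or $X^\top Y$) still error.

**Class prediction** is nearest class centroid in predictive-score space — a
rule must be fixed for accuracy statements, and the centroid rule is the
simplest one consistent with how score plots are read.

**VIP** is computed over predictive components only (orthogonal variation
is, by construction, irrelevant to class separation):
$\mathrm{VIP}_j = \sqrt{p \sum_a SSY_a (w_{ja}/\lVert w_a \rVert)^2 / \sum_a SSY_a}$.
Squared VIPs average to exactly 1, so VIP > 1 marks above-average
contributors.

### Cross-validated Q² and component selection

$Q^2 = 1 - \mathrm{PRESS}/SS$ over a seeded, class-stratified 7-fold
partition (seven folds being the de-facto convention in chemometrics
software). Scaling and the full orthogonal + predictive decomposition are
refit inside each training split — anything less leaks information. Fold
assignment is keyed to row names when present, which makes the split (and
hence Q²) invariant to sample reordering. A fold whose training split loses
an entire class is an error, not a silent skip.

When `n_orth` is not given, orthogonal components are added while Q²
improves by more than 0.01, capped at 5 — a greedy rule mirroring common
practice; the cap prevents chasing noise on small n.

### Permutation validation

`permutation_test()` refits the configuration under random label
permutations (default 200) and records R²Y and Q² against the mean
|Pearson r| between the permuted and original one-hot columns. Lines through
each statistic versus label correlation — including the unpermuted model at
correlation 1 — give intercepts at zero correlation; a negative Q² intercept
is the accepted sign that the original model's predictive ability is not an
overfitting artifact. Ordinary least squares is used for the intercepts, the
convention of the standard validation plot.

### ANOVA letters

`anova_tukey_letters()` uses `stats::aov` and `stats::TukeyHSD`, then builds
the compact letter display with the insert-and-absorb algorithm, letters
assigned in descending group-mean order. Replicate-level nesting is out of
scope: letters compare the unit the table reports (wineries within regions).

## Terroir correlation

Meteorology is aggregated as the arithmetic mean of the three stations
assigned to each region, with two-month stages averaging their months; the
aggregate is invariant to station order. Physicochemical summaries use the
$n-1$ standard deviation, matching printed mean ± sd tables. Two printed
regional averages in the packaged table differ by 0.006 from the mean of
their printed per-winery values (the source evidently averaged unrounded
triplicates); the fixtures keep both layers as printed and the tests state
the looser tolerance for exactly those two cells.

`pearson_matrix()` reports Pearson r with two-sided p from the t transform
on $n-2$ degrees of freedom. Region-level covariates are broadcast to
samples before correlating (`broadcast_regional()`); the effective n — the
number of samples, not of regions — is returned with the result, because
broadcasting inflates nominal significance and the reader should see the n
that produced each p. Zero-variance columns yield missing correlations,
never zero: "no correlation estimable" and "correlation of zero" are
different findings. No multiple-testing correction is applied by default
(single-level significance stars are the display convention);
Benjamini–Hochberg is available via `adjust = "BH"`.

## The synthetic-data generator

`generate_study()` emulates the study design: 5 regions contributing
{5, 5, 5, 6, 5} wineries, 3 fermentation replicates per winery (78
chromatography runs, collapsible to 26 winery means via `level =
"winery"` — the unit the chemometrics uses), and a ~180-compound panel.
On the natural-log scale:

* per-compound baselines $\mu_j \sim N(\log 150, 1.2^2)$, spanning roughly
  5–5000 µg/L as real wine volatile panels do;
* `n_discriminant` planted effects (default 5): compound $k$ is shifted by
  `effect_size` (default 2 log units, i.e. ≈7.4-fold) in one region,
  regions rotating — a deterministic pattern that makes ground truth
  unambiguous;
* winery-level noise sd 0.5 and replicate noise sd 0.2 (≈±65% and ±22%
  multiplicative), the former chosen as a realistic between-winery spread
  for a single-protocol fermentation study, the latter for triplicate
  repeatability;
* `n_orth_factors` (default 2) rank-1 nuisance structures whose scores are
  residualized against the region dummies — exactly class-orthogonal
  in-sample — with loadings of sd 0.3. The nuisance total (~0.18
  log-units²) is comparable to winery noise: a study run under one
  winemaking protocol, as this one was, cannot have shared nuisance
  variation dominating the signal, or its published discrimination would
  have been impossible. This gives the orthogonal filter something real to
  remove without drowning the planted effects.

Concentrations are exponentiated, so they are strictly positive and effects
are multiplicative. What the generator does **not** emulate: correlated
biochemical pathways (compounds are independent given the factors),
retention-time drift, censoring at detection limits, non-detects, or any
chromatographic artifact. Passing recovery tests therefore demonstrates the
statistical machinery works under the study's design geometry — not that
real matrices are this clean.

`generate_calibration()` mirrors the calibration design: nine
concentrations in a halving ($2^n$) dilution series with Gaussian response
noise.

## Problem sizes and determinism

All simulations are seeded and reproducible; identical (design, seed) gives
byte-identical data. The validation suite runs the full study shape
(26 wineries × 180 compounds) over 50 seeds for VIP recovery and uses 50
label permutations per seed for the permutation-intercept check; smaller
40-compound panels are used for the Q² ≤ R²Y sweep. These sizes were chosen
so the complete validation runs in a few minutes on one core while keeping
the study's n/p geometry (n ≪ p) intact — the regime in which OPLS-DA's
overfitting risks, and hence the permutation machinery, actually matter.

## Known limitations

* The OPLS orthogonal filter extracts one component per round using the
  first NIPALS component against the full class matrix; with several
  orthogonal structures of similar size the split between them is not
  unique (only their span is).
* Q² depends on the fold seed; the seed is stored in the fitted object and
  reported, but users comparing models should fix it.
* The surrogate-curve rule is purely structural (class + carbon count); it
  does not know about functional-group response factors.
* Aroma-series intensities inherit every limitation of literature
  thresholds — matrix mismatch, inter-panel variability — and should be
  read as ordinal, not ratio, measurements.
* The terroir correlations are descriptive: region-level covariates
  broadcast to samples give n = samples while the climate information has
  only as many degrees of freedom as regions. No causal reading is
  supported.
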