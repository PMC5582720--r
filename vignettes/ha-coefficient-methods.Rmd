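---
title: "The hierarchical association coefficient: model, assumptions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hierarchical association coefficient: model, assumptions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hacoef)
options(hacoef.verbose = FALSE)
```

## The statistic

`hacoef` measures the association between a positive quantitative trait and
a categorical marker on a `[0, 1]` scale. The construction:

1. **Stratification.** Order the $n$ categories by the ascending mean of
   their observations. The statistic is undefined if two category means
   coincide.
2. **Boundary decomposition.** Each of the $n - 1$ boundaries of that
   ordering splits the members into a left and right subset once the other
   boundaries are collapsed. Write $r_1$ for the observed sum of the right
   subset, and compare it with the two sorting extremes under fixed subset
   sizes: $g_1$, the sum of the $m$ largest observations (observations
   ascending across the stratified categories — the *top* arrangement), and
   $\mathrm{btm}$, the sum of the $m$ smallest (*bottom* arrangement). By
   construction $\mathrm{btm} \le r_1 \le g_1$.
3. **Distance curve.** With $y$ the total sum and $g_2 = y - g_1$, the
   hierarchical association distance is
   $d(x) = \frac{g_1}{g_2}\left(\frac{y}{x} - 1\right)$,
   a hyperbola with $d(g_1) = 1$ and its maximum over the admissible
   interval at $x = \mathrm{btm}$. It is defined only in the positive
   quadrant, which is why observations must be positive.
4. **Area ratio.** Using the antiderivative $y\ln x - x$, the boundary's
   score is the area ratio
   $\mathrm{ratio}_k = \frac{[y \ln x - x]_{\mathrm{btm}}^{\,r_1}}
                            {[y \ln x - x]_{\mathrm{btm}}^{\,g_1}} \in [0,1],$
   reaching 0 only at the bottom extreme and 1 only at the top extreme.
   The $g_1/g_2$ prefactor cancels in the ratio.
5. **Aggregation.** The coefficient is the geometric mean of the $n - 1$
   boundary ratios (default), or their arithmetic mean. Both are always
   reported; by the arithmetic–geometric mean inequality the geometric
   aggregate never exceeds the arithmetic one.

The coefficient equals 1 exactly when the observed arrangement is the top
arrangement. The value 0 requires $r_1 = \mathrm{btm}$ at every boundary,
which can only happen when the category order is fixed *independently* of
the data (`category_order`, "prehierarchical" mode): an order derived from
the data cannot place the larger observations entirely in the lower-mean
categories. Marker scans are posthierarchical, so scan coefficients are
strictly positive.

Unlike the F-test, the coefficient is a descriptive measurement, not a
test: it carries no distributional assumptions and no p-value, and the
package deliberately provides no permutation or bootstrap inference for it.

## Parameters that matter

* `tie_tol` (default `1e-12`, relative): two category means within this
  relative distance are treated as tied and the statistic is reported as
  `undefined_tied_means` rather than raising, so a genome scan can skip and
  log. Exact float equality would be brittle; the tolerance is relative so
  that rescaling the trait does not change tie decisions.
* `aggregation` (default `"geometric"`): the geometric mean keeps
  coefficients from markers with different category counts on a common
  multiplicative footing, which matters when many markers are ranked
  together; the arithmetic variant is reported alongside and tracks it
  closely.
* `shift_nonpositive` (default `FALSE`): the distance curve lives in the
  positive quadrant, so nonpositive observations are rejected. The opt-in
  shift moves the minimum to `shift_eps`. Because the coefficient is scale
  invariant but *not* shift invariant, the shifted value is a different
  statistic; the shift is logged whenever applied.
* `min_category_size` (scan only, default 1): undersized categories are
  dropped, not merged — merging would fabricate a category whose mean has
  no biological meaning. The default imposes no floor.

## Numerical choices

* Boundary ratios are computed directly from the antiderivative
  $y \ln x - x$; the geometric mean goes through `exp(mean(log(...)))`
  only when every ratio is positive, and returns exactly 0 otherwise, so
  there is no log-of-zero path and no underflow for large $n$.
* Summation order can leave the observed sum $r_1$ one ulp outside
  $[\mathrm{btm}, g_1]$ at the sorting extremes; it is pinned back into the
  interval so that the limit identities (HA exactly 1 or 0) hold exactly.
* Degenerate inputs are statuses, not crashes: `invalid_observations`
  (nonpositive values), `undefined_single_category` (fewer than two
  nonempty categories after filtering), `undefined_tied_means`. Scan
  records with a non-`"ok"` status carry `NA` statistics, never fabricated
  numbers.
* The F-test baseline is computed from per-category sums and counts
  (`SSB`/`SSW` in closed form) so the same arithmetic drives both the
  scalar and the vectorized per-column paths; agreement with
  `anova(lm(...))` to `1e-10` is part of the test suite. When the p-value
  falls below the smallest positive normal double it is clamped there and
  flagged `saturated` — the `-log10 p` scale cannot represent smaller
  values, which is exactly the right-edge failure the simulation exhibits.

## The simulation harness

`make_dataset()` regenerates the validation design: observations
$1001, 1002, \ldots, 2200$ paired with a $1200 \times 1200$ matrix of
categorical identifiers in $\{0, \ldots, c-1\}$ for $c \in \{2, 3, 4\}$.
Rows form $c$ contiguous equal blocks; in column $j$ the topmost
$\mathrm{round}(j \cdot \mathrm{blockheight} / 1200)$ rows of each block
deterministically carry the block's identifier and the remaining cells are
iid uniform over the alphabet. The deterministic ("signal") fraction grows
linearly from near 0 to 1, so each block rectangle is split into two
equal-area triangles of signal and noise, and the final column is a perfect
ascending block assignment whose coefficient is exactly 1.

Design choices the geometry leaves open, fixed here once:

* **Placement of the deterministic cells.** The coefficient depends only on
  how many members of each category fall in each block, not on row
  placement, so the deterministic cells are simply the topmost rows of each
  block. This also guarantees a fully deterministic final column.
* **Rounding.** The per-column deterministic count uses R's `round()`
  (banker's rounding at `.5`). The choice moves single cells at exact
  half-fractions and is invisible in every aggregate the harness reports.
* **Replicate seeds.** Replicate $r$ of a run uses seed
  `base_seed + r`, so a whole summary is reproducible from one integer.
* **Tied-mean columns.** A weakly structured column can draw tied category
  means by chance; such a column is excluded from that replicate's average
  and counted, never imputed.

`run_replicates()` averages per-column coefficients and $-\log_{10} p$
over replicates; `compare_variants()` runs the three designs under matched
parameters and reports the pairwise Pearson correlations of the averaged
coefficient profiles. Because the three designs share observations and
signal geometry, a sound statistic must trace the same profile three
times: at the reference scale (1200 rows, 100 replicates) the pairwise
correlations exceed 0.999, the profiles rise monotonically from a floor
near 0.6 to exactly 1, and the F-test profiles — perfectly rank-correlated
with the coefficient profiles — fail to reach the right edge because the
final deterministic columns underflow double precision.

Two contrasts between the statistics are visible only at the reference
scale and are therefore checked there in the test suite (the cheaper
profile-shape properties are checked on a 300-row, 20-replicate gate): the
p-value underflow at the final column needs roughly 600 or more rows
before the F statistic is large enough, and the *linear* correlation
between the averaged coefficient and $-\log_{10} p$ profiles rises above
0.9 for all three designs only once the clamp flattens the right half of
the p profile. Rank correlation between the two profiles is ~1 at every
scale tried.

What the harness does *not* emulate about real GWAS data: linkage between
markers, missing calls, allele-frequency spectra, covariates and
population structure, or non-uniform trait spacing. Passing it shows the
statistic responds monotonically and consistently to a controlled signal
gradient; it is not evidence about confounded designs, for which the
package also deliberately offers no correction (no multiple-testing
adjustment either — scan p-values are per-marker).

## Problem sizes in the checks

The test suite validates the closed-form areas against adaptive quadrature
on 200 random instances (up to 50 members, up to 6 categories), the
invariants (range, scale invariance at `1e-10`, bit-exact within-category
permutation invariance, AM–GM ordering, strict monotonicity in $r_1$) on
dozens of random instances under fixed seeds, and the simulation properties
on a 300-row, 20-replicate gate plus 1200-row, 5-replicate reference
checks. `scripts/acceptance.R` reruns the full reference protocol
(1200 × 1200, 100 replicates, all three designs, ~1 minute).

## Known limitations

* Tied category means make the coefficient undefined; with continuous
  traits this is rare, but heavily discretized traits can trigger it.
* The coefficient is shift sensitive: adding a constant to the trait
  changes it (the distance curve is anchored at the origin). Compare
  coefficients only across markers measured on the same trait scale.
* Posthierarchical coefficients have a data-dependent lower bound well
  above 0 (near 0.6 in the triangle designs); the coefficient is a
  within-scan ranking device, and its absolute scale should not be read as
  a calibrated effect size.
* No inference is attached to the coefficient; use the bundled F-test (or
  any external test) when a p-value is required.
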