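---
title: "Measuring allocation equity over area and population: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allocation equity over area and population: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equigeo)
```

## The problem

Whether a health or aged-care resource is allocated "fairly" depends on the
question asked. Allocation proportional to the *target population* addresses
availability: every older adult has, on average, the same number of beds or
professionals behind them. Allocation proportional to *geographical area*
addresses accessibility: in a sparsely populated, very large region,
population-proportional allocation can leave residents hundreds of kilometres
from the nearest institution. `equigeo` quantifies both readings on
region-level tables — one row per administrative unit with its area
(10,000 km² in the bundled data), its population aged 65 and above, and one
or more non-negative resource counts.

## Agglomeration degrees

For unit $i$, resource total $HR_i$, area $A_i$ and population $P_i$, with
territory totals $HR_n, A_n, P_n$:

$$\mathrm{HRAD}_i = \frac{HR_i/A_i}{HR_n/A_n}, \qquad
  \mathrm{PAD}_i = \frac{P_i/A_i}{P_n/A_n}, \qquad
  \frac{\mathrm{HRAD}_i}{\mathrm{PAD}_i} = \frac{HR_i/P_i}{HR_n/P_n}.$$

HRAD compares a unit's resource density per unit area with the national
density; its ratio to PAD compares per-capita rates instead, because the
areas cancel. The package computes the ratio directly from the populations
rather than by dividing the two degrees, avoiding an unnecessary
rounding step (the two routes agree to $10^{-9}$ and a test asserts it).
Values are classified over-allocated ($>1$), absolutely equitable ($=1$) or
under-allocated ($<1$). Exact equality is a measure-zero event on real data,
so the $=1$ band is implemented as $|v-1|\le 10^{-9}$; real tables will
essentially never hit it, which is the intended behaviour of a criterion
stated on exact equality.

Two identities pin the construction down and serve as invariant tests: the
area-weighted mean of HRAD and the population-weighted mean of HRAD/PAD are
exactly 1 on any valid table.

**Totals convention.** $HR_n, A_n, P_n$ are *column sums over the table*, not
externally supplied national figures. On the bundled data this convention
reproduces every published 3-decimal agglomeration value (e.g. Shanghai's
institution HRAD of 26.803 back-solves to the summed area 963.14), so it is
locked in; a user who wants different denominators can append a row or scale
the table.

## Lorenz curves and the trapezoid Gini

Units are ranked ascending by resource density — count per unit area for the
area dimension, count per person for the population dimension — and the
cumulative denominator share $X$ is plotted against the cumulative resource
share $Y$ from $(0,0)$ to $(1,1)$. With ascending sorting the curve lies on
or below the equality diagonal, and

$$G = 1 - \sum_i (X_i - X_{i-1})(Y_i + Y_{i-1})$$

is twice the area between curve and diagonal (trapezoid rule, exact for the
piecewise-linear grouped-data curve). Bands: $G<0.2$ absolute equity,
$0.2$–$0.3$ equity, $0.3$–$0.4$ basic equity, $0.4$–$0.5$ inequity, $\ge 0.5$
high inequity.

Numerical choices:

* **Tie-break.** Units with identical densities are ordered by name. The
  choice is for determinism only — $G$ is provably unchanged by tie order,
  and a test permutes tied rows to confirm it.
* **Endpoint pinning.** The final cumulative shares are set to exactly 1 to
  absorb last-ulp drift from the running sums.
* **Degenerate inputs.** Zero-count units are legal and sort first (density
  0); an all-zero resource column has no Lorenz curve and is an error.
  Zero areas or populations are schema errors caught by `validate_provinces()`.
  A tiny negative $G$ (below $10^{-9}$ in magnitude, from float cancellation
  on perfectly equal tables) is clamped to 0.
* **Granularity.** $G$ is computed at the granularity of the table's rows
  (province level in the bundled data; 11/8/12 units within regions). No
  within-unit disaggregation is attempted, so the values are grouped-data
  Ginis and would rise under finer partitions.
* **Rounding.** Full precision is kept everywhere; print methods display
  3 decimals (half-up, matching how such tables are conventionally printed),
  and exports carry full precision.

**Independent oracle.** The same quantity is implemented a second time as the
pairwise weighted mean absolute difference
$G = \sum_{ij} w_i w_j |r_i - r_j| / (2 W^2 \bar r)$ with rates
$r_i$ = count/weight. The two code paths share nothing (no sorting, no
cumulative sums on the oracle side) and are required by the test suite to
agree to $10^{-12}$ on a thousand randomly generated tables.

**Within-region analyses** subset the table first and recompute all totals on
the subset, so a region's Gini measures inequality *among its own units*
relative to its own aggregate. On the bundled data this convention reproduces
all 24 published regional cells at 3 decimals.

## The bundled 2020 dataset

`builtin_china_2020()` returns the 31-province mainland-China table for 2020:
four resource indicators (care institutions 38,158; employees 518,185;
professional staff 378,897; beds 4,882,366), areas, populations aged 65+
(191 million in total), staff age and education counts, and the standard
eastern/middle/western partition (11/8/12 units). It was transcribed from the
published per-province tables; the package's reproduction tests check every
cell of the derived statistics against the published 3-decimal values within
print-rounding tolerance. One published cell disagrees with its own inputs:
the employees-by-area Gini computes to 0.7256 but is printed as 0.727; the
package reports the computed value.

## The synthetic generator

`generate_provinces()` emulates the *structure* the statistics assume, at the
scale of the bundled study (defaults: 31 units; four resources with expected
per-1,000 rates 0.20 / 2.72 / 1.99 / 25.61, the national rates of the 2020
table):

* areas log-normal (median 17, log-sd 1.3 — the bundled areas span
  0.63–166 with roughly that spread);
* population = area × log-normal density (median 3×10⁵ persons per
  10,000 km², log-sd 1.5, matching the three-orders-of-magnitude density
  range of the real table);
* resource count = population × log-normal per-capita rate, rounded; the
  log-sd `resource_rate_sigma` (default 0.5, about the observed dispersion of
  per-capita institution rates) is the single inequality knob. At 0 all units
  share one rate and the population-dimension Gini collapses to rounding
  noise; the mean Gini rises monotonically in sigma, which a 200-seed
  Monte-Carlo test verifies per level on a {0, 0.2, 0.5, 1.0} grid.

One root seed drives all draws through R's Mersenne–Twister with fixed
normal/sample kinds, so identical configurations give identical tables across
platforms, and the caller's RNG state is restored afterwards.

What the generator does **not** model: spatial autocorrelation between
neighbouring units (the statistics are exchangeable over rows, so none of
them could detect it), correlation between area and population density,
heavy-tailed deviations from log-normality, and reporting artefacts of real
yearbook data. Passing property tests on synthetic tables therefore
establishes the *mathematics* of the implementation, not the realism of any
particular inequality level.

`two_group_table(p, q, dimension)` builds the minimal closed-form harness: a
two-unit table whose Lorenz curve has a single kink at $(p, q)$, giving
$G = p - q$ exactly (shares are realised on a $10^{8}$ grid, so $p$ and $q$
with up to 8 decimals are exact). `staff_structure_synth()` draws multinomial
age bins that conserve the employee total and education counts bounded by it.

## Design decisions that were genuinely open

* **Totals as column sums** (above) rather than external national figures.
* **CSV dialect**: UTF-8, comma-separated, header mandatory, decimal point,
  no thousands separators; areas stay in units of 10,000 km², no conversion.
* **Staff bins**: age-bin/employee-total mismatches are warnings, not errors,
  so partial staff breakdowns in user data survive validation; the bundled
  data passes with zero warnings (every province's four bins sum exactly to
  its employee count).
* **Regional table defaults**: the pipeline computes within-region Ginis for
  every region label with at least two units and skips the table when fewer
  than two labels qualify, so the bundled analysis reproduces with zero
  arguments and small toy tables do not error.
* **Export determinism**: the run timestamp lives only in
  `run_metadata.json`; every table and Lorenz file is byte-identical across
  re-runs on the same input.

## Problem sizes used by the test suite

Reproduction tests run on the 31-unit bundled table (well under a second for
the full pipeline). Property tests use 1,000 random tables of 2–25 units for
the oracle equivalence, a 55-point $(p,q)$ grid for the closed form, and
4 × 200 generator draws at 31 units for the dispersion-monotonicity check —
sizes at which the grouped statistics are fully exercised while the whole
suite stays interactive.

## Limitations

* The statistics treat resources as homogeneous; service quality and
  capacity differences between institutions are invisible to them.
* Grouped-data Ginis depend on the partition; comparisons are only valid
  between analyses at the same granularity.
* No inferential machinery (bootstrap intervals, dominance tests) is
  provided; all reported values are point descriptions of one table.
* The equity bands are the conventional income-inequality thresholds; no
  domain-specific calibration for aged-care resources exists.
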