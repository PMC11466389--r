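---
title: "Characterizing sewershed populations: models, aggregation rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing sewershed populations: models, aggregation rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sewershedpop)
```

## The problem

Wastewater-based epidemiology infers community health from samples taken at
wastewater treatment plants. Each sampling point observes one *sewershed* —
the area whose wastewater drains to that plant — so the population a
monitoring program actually "sees" is the population living inside its
sewershed polygons. Whether that population resembles the county or state it
is taken to represent, and whether sewered residents resemble unsewered
ones, are health-equity questions: if monitored populations are
systematically richer, whiter, or less vulnerable than the community,
wastewater signals will misrepresent community disease burden.

`sewershedpop` implements the geospatial workflow for answering these
questions:

1. **Delineation** — union the sewershed polygons within a county (clipped to
   the county), and erase that sewered area from the county to obtain the
   unsewered remainder.
2. **Selection** — attach census blocks and tracts to each analysis region by
   spatial intersection.
3. **Aggregation** — dissolve the selected units into one profile per region
   under per-variable rules (below).
4. **Comparison** — difference the profiles, flag meaningful differences, and
   attach margin-of-error-based significance.

Because real sewershed boundary data is restricted and full census extracts
are bulky, the package ships a synthetic census-geography generator that
reproduces the *statistical structure* of those inputs with exported ground
truth, so the full pipeline is testable at desk scale.

## The data model

Twenty-three variables span five conceptual domains (demographics, health,
housing & transportation, social vulnerability indices, socio-economic
status). Their measure kind determines how they aggregate and compare:

| measure | examples | level | aggregation | comparison |
|---|---|---|---|---|
| count | race/ethnicity, group quarters | block | sum, then share of total | pp difference |
| percentage | poverty, disability, 65+, ... | tract | mean over tracts | pp difference |
| currency | median household income | tract | mean of tract medians | % difference |
| percentile rank | SVI overall + 4 themes | tract | population-weighted mean | rank points (×100) |

Count variables carry no margins of error (decennial census), nor do SVI
ranks; the ten ACS percentage variables and income do. A region's profile is
therefore a vector of 23 values, a subset of which have MOEs.

Aggregation formulas, for selection weights $w_i$ (all 1 under plain
intersect selection; area fractions under area-weighted apportionment):

* counts: $100 \cdot \sum_i w_i v_i / \sum_i w_i d_i$ with denominator $d$
  the block population;
* percentages (default): $\sum_i w_i p_i / \sum_i w_i$, the dissolve-style
  average of tract percentages; optionally
  $\sum_i w_i n_i p_i / \sum_i w_i n_i$ (population weighted), which
  estimates the person-level share — both modes are provided, the
  unweighted mean is the default for fidelity with the dissolve convention,
  and the output metadata records which was used;
* income: unweighted mean of tract medians (an *average median*, not a
  pooled median);
* ranks: $\sum_i w_i n_i r_i / \sum_i w_i n_i$.

Margins of error combine by root sum of squares,
$\mathrm{MOE}_{\Sigma} = \sqrt{\sum_i m_i^2}$, which is exact for sums of
independent estimates. For an unweighted mean of $k$ estimates the package
uses $\mathrm{MOE}_{\Sigma}/k$ (more generally
$\sqrt{\sum_i (w_i m_i)^2} / \sum_i w_i$), the standard error propagation
for a weighted mean; the plain root-sum-of-squares rule is stated for sums,
and dividing by $k$ is the interpretation that makes the mean's MOE
consistent with it.

## Comparison statistics

The difference convention is always *monitored/sewered side minus
reference*. Categorical variables (counts, percentages) are compared in
percentage points; income as a percent difference
$100\,(a-b)/b$; SVI ranks as rank differences scaled by 100 so that one
threshold applies everywhere. A difference is **meaningful** when
$|\Delta| > 5$ (strictly; the boundary value is not flagged — "greater
than ±5" is read literally, and the threshold is configurable).

Significance uses the survey-estimate MOE algebra: published 90%-confidence
MOEs are converted to standard errors by dividing by 1.645, the SE of a
difference is the root sum of squares of the two SEs, and
$Z = \Delta / SE$ earns stars at $|Z| > 1.96$ (\*), $2.58$ (\*\*),
$3.29$ (\*\*\*). Two details deserve note:

* For income the *meaningful* flag is based on the percent difference but
  $Z$ is computed from the raw dollar difference against the dollar-scale
  combined MOE — mixing a relative difference with an absolute MOE would be
  dimensionally wrong.
* The simpler screening rule ("difference exceeds twice the MOE") is
  implemented as $|\Delta| > 2\sqrt{m_a^2+m_b^2}$, i.e. twice the combined
  MOE. The alternative reading (twice each MOE separately) is noted in the
  function documentation; the combined form matches the package's MOE
  algebra.
* Variables without published MOEs (decennial counts, SVI ranks) get
  meaningful flags only, never stars.

## Geometry

All computational geometry is planar and rectilinear: geometries are unions
of axis-aligned rectangles, and union/intersection/erase are computed
exactly by slab decomposition over the x breakpoints. This engine is built
into the package; it covers every shape the synthetic generator produces
(blocks, tracts, counties and sewersheds are rectangles, and everything
derived from them stays rectilinear), conserves area to floating point
(the erase conservation assertion is at 1e-9 relative), and is validated
against an independent raster-counting oracle in the test suite. Real-world
curvilinear shapefiles are outside this engine's scope; the I/O layer
rejects non-rectilinear rings explicitly rather than approximating them.

Selection uses a *positive-area* intersection predicate: units sharing only
a boundary line with a region are not selected. Desktop-GIS
select-by-intersect semantics differ on exactly this point, so a
`include_touching` flag is provided for sensitivity analysis. Under plain
intersect selection a unit straddling the sewered boundary is counted
whole on *both* sides — the whole-unit convention knowingly overestimates
sewershed populations, and the test suite asserts that direction of error.
The area-weighted mode apportions straddling units by overlap fraction and
exactly conserves county totals across the sewered/unsewered partition.

## The synthetic generator

`synthetic_config()` / `generate_state()` build a nested geography: square
1 km blocks tiling square tracts tiling square counties laid side by side,
with one rectangular sewershed (optionally several strips) anchored at each
county's lower-left "urban core" corner, covering `sewered_fraction` of the
county's area. The sewershed width is stretched by 7% off the block lattice
so boundary-straddling census units always exist — the apportionment
problem is generated on purpose.

Attribute models (all parameters are `synthetic_config()` arguments):

* **Block counts.** Population is Poisson(`mean_block_population`);
  race/ethnicity counts are one multinomial draw per block. The composition
  is the baseline vector outside sewersheds; inside (block centroid in the
  sewershed), categories named in `gradient_spec` are shifted by the given
  percentage points and the remaining categories are renormalized.
  Categories are generated exhaustive and mutually exclusive so the
  sum-to-total invariant is exactly testable (real redistricting data is
  not, and the data model does not require it for real inputs).
* **Tract percentages.** Each tract's true value mixes the sewered and
  unsewered regimes by its latent sewered population share, then receives
  binomial-scale sampling noise with effective sample size
  `n_eff = n_eff_scale × population`; the published MOE is
  `1.645 × sqrt(p(1-p)/n_eff) × 100`. There is deliberately *no*
  cross-tract heterogeneity beyond the gradient: the reported MOE then
  accounts for all noise, giving the Z statistic a correct null — this is
  what makes the calibration test meaningful. Real ACS tracts are
  heterogeneous, so passing calibration here validates the MOE algebra,
  not the homogeneity of real data.
* **Income.** Log-normal across tracts (`income_sigma_log`, default 0.10 —
  kept modest so recovery experiments are precise; real income dispersion
  is larger) with a multiplicative sewered shift, plus a relative sampling
  error `income_se_scale/sqrt(n_eff)` covered by the MOE. Because the
  cross-tract dispersion is real signal the MOE does not cover, income is
  excluded from the null-calibration tally — exactly as a Z test on
  aggregate income means over real tracts would be anticonservative.
* **SVI ranks.** Latent standard-normal vulnerability scores per theme,
  shifted by `gradient_spec` (in SD units) inside sewersheds; the overall
  score combines the themes. Each score vector is ranked across all tracts
  and scaled to exactly `{0, 1/(T-1), ..., 1}` (ties broken by tract
  order), so rank uniformity is exact.

The default configuration represents the study conditions the generator
emulates: a nine-county sewered/unsewered design, 16 tracts per county, 16
blocks per tract, ~250 people per block (~4,000 per tract), 30% sewered
area, and a gradient making sewered areas more African American and
Hispanic, poorer, denser-housed, and more vulnerable. Ground truth exports
the design-level sewered/unsewered value and difference per variable
(count-variable truth is computed from the realized block counts;
tract-variable truth is the design value, since sampling noise is what the
pipeline is supposed to average away) plus latent per-region populations.

## Numerical and design choices

* **Rounding.** The coverage table's integer percent-monitored column uses
  round-half-away-from-zero (`round_half_away()`), the commercial rounding
  used in published coverage tables; base R's half-to-even does not
  reproduce them.
* **Thresholds.** Meaningful means strictly greater than 5 (pp, %, or rank
  points); stars use strict inequalities at 1.96/2.58/3.29.
* **Degenerate inputs.** Zero aggregate denominators yield *absent* values
  (NA), never zero; empty selections yield empty profiles; a fully sewered
  county yields an empty unsewered region which is simply skipped in
  comparisons; both MOEs zero makes Z undefined and is an error.
* **Reference profiles** (county, state) are computed by the same dissolve
  over all their units rather than from separately published tables, for
  methodological symmetry.
* **Strict joins.** A polygon without attributes is an error by default;
  lenient mode drops and reports. Silent drops would bias equity
  comparisons. A tract missing one estimate is excluded from that
  variable's aggregate only.
* **Capacity filter.** The sewered-area merge includes only plants with
  `design_flow_mgd ≥ 0.5` when the attribute is present, mirroring the
  municipal-plant inclusion rule; synthetic sewersheds carry the attribute
  (with a floor above the filter, since they represent qualifying
  municipal plants).
* **Coverage populations.** Utility-reported service populations and
  census-derived totals are both carried but never mixed within one
  computation; the coverage table records which source it used.

## What the tests do and do not show

The test suite validates the pipeline's arithmetic and statistics at desk
scale: published coverage percents are reproduced exactly from the bundled
monitoring table; every aggregation rule matches brute-force enumeration;
the area-weighted partition conserves county totals to 1e-9 while plain
intersect selection double-counts straddlers in the documented direction;
Z statistics on null synthetic data reject at the nominal ~5% rate (1,000
cross-county comparisons — cross-county pairs keep the two sides disjoint,
since sharing a straddling tract between sewered and unsewered profiles
correlates their errors); and injected gradients (+10 pp minority share,
−20% income) are recovered by the full pipeline under area-weighted
apportionment. Problem sizes used: a 12-county state with 256 tracts per
county for recovery precision (~6M synthetic residents), 100 four-county
replicates for detection reliability, 50 replicates for calibration.

Recovery experiments use area-weighted apportionment deliberately: the
whole-unit intersect convention dilutes a boundary gradient by
double-counting straddlers — that bias is a property of the convention
(the package reproduces and documents it), not of the estimator used to
check recovery.

What passing these tests does *not* show: performance on curvilinear
real-world geometry, robustness to ACS design effects or differential
privacy noise in decennial counts (the generator models neither), or the
behavior of percentile ranks under re-ranking of a subset of tracts.
The generator's distributions are artifact choices — documented, fixed, and
not inferred from any real dataset.

## A worked example

```{r example, eval = FALSE}
library(sewershedpop)

cfg <- pipeline_config(
  data_dir = "fixture", out_dir = "results",
  synthetic = list(n_counties = 4, seed = 42))

run_simulate(cfg)   # nested blocks/tracts/counties + sewersheds + truth
run_profile(cfg)    # per-region profiles + coverage table
run_compare(cfg)    # four framings of comparison records
run_report(cfg)     # human-readable summary from the CSVs
```

The same stages are scriptable from a shell through
`inst/cli/sewershed-cli.R`, a thin `optparse` wrapper with subcommands
`simulate`, `profile`, `compare`, `report`, reading one YAML/JSON config
with flag overrides (flags > config > defaults) and returning exit code 1
for validation errors and 2 for I/O errors.
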