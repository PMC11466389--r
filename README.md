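# sewershedpop

Who does wastewater monitoring actually monitor? Each sampling site at a
wastewater treatment plant observes one **sewershed** — the area whose
wastewater drains to that plant — so the population represented in
wastewater data is the population living inside the sewershed polygons.
`sewershedpop` characterizes those populations and compares them with the
counties and states they are taken to represent, and compares sewered with
unsewered residents, to support health-equity assessments of
wastewater-based epidemiology programs.

The package implements the full geospatial workflow:

* **Delineation** — union a county's sewershed polygons (clipped to the
  county) into a sewered area; erase it from the county to get the
  unsewered remainder. Geometry is an exact rectilinear (axis-aligned)
  boolean engine built into the package.
* **Selection** — attach census blocks/tracts to regions by spatial
  intersect (whole-unit weights, the classic convention that overcounts
  boundary units) or by area-weighted apportionment (which conserves
  county totals).
* **Aggregation** — dissolve selected units into a 23-variable profile per
  region: block counts are summed then expressed as shares
  (100·Σwv/Σwd), tract percentages averaged, median household income
  averaged over tract medians, SVI percentile ranks population-weighted
  (Σw·n·r/Σw·n); margins of error combine by root sum of squares
  (√Σm², divided by k for a mean of k estimates).
* **Comparison** — differences are monitored/sewered minus reference:
  percentage-point differences for categorical variables, percent
  difference 100(a−b)/b for income, rank points (×100) for SVI. A
  difference is *meaningful* when |Δ| > 5 (strict), and significance stars
  follow Z = Δ/SE with SE = √(m₁²+m₂²)/1.645 and thresholds
  |Z| > 1.96 (\*), 2.58 (\*\*), 3.29 (\*\*\*).
* **Synthetic geography** — a generator for nested blocks → tracts →
  counties with rectangular sewersheds, configurable demographic gradients
  (e.g. sewered areas with higher minority share, lower income, higher
  vulnerability), ACS-style margins of error with a correct null, and
  exported ground truth — so the entire pipeline is testable without any
  restricted data.

Four comparison framings are orchestrated end to end: all monitored
sewersheds vs the state; each county's combined sewersheds vs the county;
each individual sewershed vs its county; and each county's sewered vs
unsewered area.

## Worked example

```r
library(sewershedpop)

cfg <- pipeline_config(
  data_dir = "fixture", out_dir = "results",
  synthetic = list(n_counties = 4, seed = 42))

run_simulate(cfg)   # writes blocks/tracts/counties/sewersheds + truth
run_profile(cfg)    # per-region profiles + coverage table
run_compare(cfg)    # comparison records for the four framings
run_report(cfg)     # report.md derived from the CSVs
```

This prints, among other things:

```
simulate: wrote 1024 blocks, 64 tracts to fixture
profile: 17 region profiles, 4 coverage rows
compare: 299 records across 4 framing(s)
```

The coverage table gives each sewershed's service population, its county
population, and the integer percent monitored (28% for all four counties
here, since each synthetic sewershed covers ~30% of its county):

```
  region_id county_id combined sewershed_population county_population
1 C01-S1    C01       FALSE                   18147             63826
2 C02-S1    C02       FALSE                   17670             63657
```

Under the default gradient, the sewered-vs-unsewered framing for county
C01 shows the generated contrasts:

```
                 variable  value_a  value_b   diff diff_units meaningful
        african_american  29.26    20.93     8.334         pp       TRUE
                hispanic  18.63    12.07     6.558         pp       TRUE
 median_household_income  54470    55150    -1.228    percent      FALSE
             svi_overall  0.6672   0.4058   26.142         pp       TRUE
```

African American and Hispanic shares are ~8 and ~7 pp higher in the
sewered area (the generator injected +10 and +8 pp; whole-unit intersect
selection dilutes boundary effects — exactly the documented overcount of
the intersect convention), and the overall SVI rank is 26 rank points
higher. The income estimate at this small size is dominated by cross-tract
income dispersion (9 tracts per sewered area); the recovery experiments in
the test suite show that at larger sizes, under area-weighted
apportionment, injected gradients are recovered to within a fraction of a
percentage point. The report summarizes each framing in
"X of 23 variables not meaningfully different" form:

```
* sewered_vs_unsewered: 14 of 23 variables not meaningfully different in any region pair.
* sewersheds_vs_state: 16 of 23 variables not meaningfully different in any region pair.
```

A thin command-line wrapper (`inst/cli/sewershed-cli.R`) exposes the same
four stages as subcommands reading a YAML/JSON config.

The bundled `ncwmn_coverage()` table carries the published service and
county populations of the 25 sewersheds monitored by the North Carolina
Wastewater Monitoring Network as of June 2022; `percent_monitored()`
reproduces its integer coverage column exactly (e.g. City of Wilson:
49,384 of 81,801 → 60%).

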