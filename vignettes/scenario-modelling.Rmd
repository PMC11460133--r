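---
title: "Methods: scenario modelling of school-based PA interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scenario modelling of school-based PA interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolPA)
```

## The model

`schoolPA` compares secondary-school interventions by their projected effect
on five determinants of future physical activity (PA) in an adolescent
survey population: weekly PA duration (hours/week), number of PA settings
per week, number of PA types per week, a physical literacy score (scale
minimum 4, default maximum 20) and a social support score (scale minimum 5,
default maximum 25). The pipeline is deliberately simple and fully
design-based:

1. draw (or load) a survey sample of 12–17-year-olds and keep secondary
   school / Kura Kaupapa attendees;
2. calibrate sampling weights to known population margins by iterative
   proportional fitting (IPF, "raking");
3. estimate each determinant's population mean with a Hájek ratio mean and a
   Taylor-linearised cluster-robust standard error;
4. apply each intervention's effect specification to its eligible
   participants and re-estimate, giving a delta and percent change per
   determinant;
5. rank interventions per determinant on a scorecard and cost national
   rollout in NZD 2019.

The estimand at every step is a population mean under the survey design;
no outcome model is fitted, so the scenario comparison inherits the survey's
assumptions (weights correctly calibrated, clusters are the relevant PSU
level) rather than regression assumptions.

## The synthetic population

The generator (`generate_population()`) stands in for restricted survey
microdata. It draws independent sociodemographics per participant at the
analytic sample's composition: six age bands (1.8%–24.9%), gender
(male/female/diverse = 42.6/56.6/0.8%), multi-select ethnicity as
independent Bernoulli indicators (Māori 13.8%, European 84.5%, Pacific 4.7%,
Asian 11.4%, other 2.5%; an empty draw is assigned European so the set is
never empty), physical disability (6.1%) and neighbourhood deprivation
(low/mid/high/unknown = 37.1/32.4/14.4/16.1%; the published composition has
0.4% missing, folded here into "unknown" so the distribution sums to one).
School attendance is Bernoulli at 5035/6906, matching a 6,906-person survey
frame with a ~5,035-person analytic sample. PE participation declines
linearly with age from 0.95 at 12 to 0.35 at 17 — a configurable placeholder
that reflects the well-known PE drop-off without asserting unpublished
national figures.

Determinant outcomes are generated with simple shapes on the correct
supports, each centred on a configurable national target mean:

* **Weekly PA hours** — gamma with shape 1.5 (right-skewed, non-negative;
  SD ≈ 0.8 × mean, a realistic dispersion for self-reported weekly hours).
* **Settings and types counts** — binomial over a finite checklist
  (`settings_size = 8`, `types_size = 20` items) with `p = mean/size`. These
  quantities are counts of distinct items ticked on a bounded survey
  checklist, so a binomial is the natural generative model; it also has the
  right (slightly sub-Poisson) dispersion for bounded multi-select counts.
* **Scores** — normal truncated to the scale bounds, with the latent mean
  solved (by `uniroot` on the truncated-normal mean, tolerance 1e-12) so the
  post-truncation mean equals the target; latent SD 2.5 score points.

A cluster structure of 100 PSUs nested round-robin in 16 districts carries a
small normal random intercept per determinant (default SD = 1% of the target
mean). This makes the design non-degenerate — cluster-robust variances are
estimated on real between-cluster variation — while keeping the intraclass
correlation realistic for a broad national school survey (< 1–2%).

**What the generator does not emulate:** correlations between
sociodemographics (age × ethnicity × deprivation are independent here),
sociodemographic gradients in the determinants (hooks exist via
`determinant_shifts`, but defaults are unstratified), non-response, and any
design weighting beyond a self-weighting sample (`base_weight = 1`). Tests
passing on this population therefore validate the pipeline's arithmetic and
its statistical calibration (CI coverage, margin recovery), not substantive
conclusions about any real adolescent population.

## Raking

`ipf_rake()` cycles over margins in their configured order, rescaling
weights within each margin's categories to match the known totals, until the
maximum relative margin deviation is ≤ `tol` (default 1e-8, far below any
reporting precision) or `max_iter = 200` cycles. Margins must be mutually
consistent (equal grand totals within 1e-6 relative) and feasible (every
category populated); violations raise errors naming the offending category.
Because ethnicity is multi-select it cannot partition the sample, so the
shipped ethnic-group margin uses a prioritised single-select derivation
(Māori > Pacific > Asian > Other > European), mirroring the prioritised
output convention of NZ ethnicity statistics — users supplying their own
margins should be aware the prioritisation is a modelling choice. No weight
trimming is applied (a no-op hook exists in the sense that trimmed weights
can be passed straight to the estimators).

## Estimation

For weights $w_i$ and values $y_i$, the Hájek mean is
$\bar y_w = \sum w_i y_i / \sum w_i$. Its linearised variance uses per-unit
scores $z_i = w_i (y_i - \bar y_w) / \sum w_i$ aggregated to cluster totals
$Z_c$, with the ultimate-cluster estimator
$\hat V = \frac{m}{m-1} \sum_c (Z_c - \bar Z)^2$ for $m$ clusters, and a
$t_{m-1}$ reference for confidence intervals — the conventional design
degrees of freedom for a single-stage cluster sample with one implicit
stratum. Calibrated weights are treated as fixed in the variance (no
calibration adjustment), matching common practice when raking is not encoded
in the variance estimator. No finite-population correction is applied. Under
equal weights and singleton clusters the estimator reduces exactly to
$s^2/n$, which the tests verify to 1e-12, and at 100 clusters it agrees with
a 5,000-replicate cluster bootstrap within 10% and attains 93–97% empirical
coverage at nominal 95% over 2,000 Monte Carlo replicates.

## Intervention scenarios

Eligibility is a conjunction: school attendance, PE participation when the
intervention is PE-only (TAPE), and an inclusive age range (PL: 13–14).
Effects are applied per determinant in absolute units or as relative
multipliers, with optional age/gender strata overrides.

Two effect presets ship with the package:

* **calibrated** — the published national-level changes (e.g. +0.2 h/week
  for NE; +3.6% physical literacy for PL) are back-solved at run time into
  constant per-eligible absolute effects, `effect = delta / share`, where
  `share` is the eligible weight share and percent-reported score targets
  are first converted via the baseline mean. By linearity of the weighted
  mean this reproduces the aggregate deltas exactly. The calibrated preset
  sets `clamp = FALSE`: projecting individual values onto their valid ranges
  (e.g. flooring hours at zero for PL's negative effect) would bias the
  aggregate delta and break the exact inversion, so clamping and the exact
  reproduction of published aggregates are deliberately mutually exclusive.
  Calibrated effects are a reproduction device for the aggregate results,
  not estimates of individual-level effect sizes.
* **illustrative** — round-number effects with `clamp = TRUE` for tutorials,
  where counts are rounded half away from zero and all values are projected
  onto their supports.

The scorecard ranks deltas per determinant (rank 1 = largest), breaking ties
deterministically by intervention name.

## Costing

Each cost component (amount, currency, year) is CPI-adjusted within its
source currency to 2019 and then PPP-converted to NZD — CPI before PPP, the
standard health-economics order. Reporting rounds half-up to the cent only
at output boundaries (internal arithmetic is full precision): per-student
cost is per-school / 740 (the 2019 average secondary-school roll), national
rollout is per-school × 376 schools. The shipped CPI/PPP tables
(`inst/extdata/*_synthetic.csv`) are synthetic calibration values,
back-solved so the conversion reproduces the published per-school NZD-2019
figures from their published source amounts; they are not OECD statistics,
and users converting other costs should substitute real series.
`check_cost_consistency()` surfaces the one internal inconsistency in the
published cost table — a per-school cost of NZD 88,755 implies 119.94 per
student, not the printed 119.40 — rather than matching it.

## Numerical and degenerate-input conventions

* Percentages in the demographic table round half-up to one decimal;
  currency rounds half-up to the cent.
* Raking on weights that already satisfy the margins returns them unchanged
  (a fixed point); a single margin converges in one pass
  (post-stratification).
* A single cluster is a degenerate design and raises an error rather than
  returning a 0/0 variance; constant outcomes yield SE 0 and a degenerate
  CI.
* Count determinants are stored as numeric so scenario arithmetic never
  retypes columns; with clamping off, post-intervention counts may be
  fractional (population-average shifts).
* Zero-width CIs are drawn as whiskerless points in the estimates figure.

## Problem sizes

The test suite regenerates all fixtures in code: full 6,906-person
populations for distributional checks (100–200 seeds where a rate is
asserted), ≤ 6-participant fixtures for exact raking oracles, 100-cluster
synthetic designs for the bootstrap comparison (5,000 replicates) and CI
coverage (2,000 replicates). These sizes were chosen to make the Monte Carlo
error of each asserted rate small relative to its acceptance band.

## Limitations

* Independence of sociodemographics and unstratified determinant baselines
  understate real-population heterogeneity; effect-modification by
  age/gender is supported but defaults to none.
* The calibrated preset reproduces aggregate changes by construction; it
  cannot validate unpublished individual-level effect sizes, intervention
  decay over time, or longitudinal projection into adulthood, all of which
  are out of scope.
* Cost-effectiveness analysis is out of scope; costs are descriptive.
* The raking margins shipped by default (district × gender, prioritised
  ethnic group) are a minimal plausible set; the true margin set of any
  specific survey should be configured explicitly.
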