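---
title: "Measuring health-need inequality in commercial geospatial data availability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health-need inequality in commercial geospatial data availability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoequity)
```

## The problem and the study design

Healthcare planning with GIS leans on three families of commercial data:
geocoding reference data to locate patients' residences, road-network and
traffic data to compute patient travel times, and small-area statistics to
characterise neighbourhoods. `geoequity` implements a cross-sectional
ecological analysis of how the availability of those resources lines up
with health need: countries are the units internationally (outcome:
age-standardised all-cause and cause-specific mortality), districts are the
units in sub-national case studies (outcome: the geocoding success rate for
facility place-names, with area deprivation as the ranking variable).

Being ecological and cross-sectional, the analysis describes gradients, not
causes: a negative concentration index says mortality is concentrated where
commercial data are scarce, nothing more.

## From coverage statements to an index

Provider coverage statements arrive as ordered categories (a geocoding
service might resolve "address points" in one country and only "localities"
in another). The packaged catalog (`default_catalog()`) records, for each
of five geocoding indicators, five travel indicators and three
neighbourhood measures, the ordered level set from worst to best plus a
reference count of countries at each level; the counts sum to the
183-country reference total. Three scoring conventions matter:

* **Absence is a level, not missingness.** A provider that publishes no
  service for a country is scored at the worst level ("no service" rows
  are part of the level sets). The one exception is areal-statistics
  population: where the provider has no data the national population
  stands in (flagged `fallback`), since the relevant quantity — mean
  population per areal unit — degenerates to the whole country.
* **Only order matters.** Scores are 1-based level positions; any strictly
  monotone rescoring leaves every downstream index unchanged (a tested
  property), because aggregation is rank-based.
* **Composites.** The travel-quality composite sums five components
  (traffic, speed limits, cycling, walking, driving directions) scored
  2 / 1 / 0 for good / approximate / otherwise, range 0–10. Geodemographic
  availability counts available products (two consumer classifications
  plus a demographic data set), range 0–3; the alternative of keeping the
  third product as a separate indicator would change the geocoding-domain
  weighting of the rank sum and is not the default.

Each indicator ranks countries with rank *n* = best availability and ties
averaged. Mean ranks keep the rank total at exactly *n*(*n*+1)/2, which
matters because ties dominate when 183 countries occupy four to six levels:
a completely tied indicator then contributes exactly (*n*+1)/(2*n*) ≈ 0.5
per indicator to the domain index rather than an arbitrary value. The
domain index divides the summed ranks by the maximum possible *K·n*; the
overall index sums the three domain values so that a domain with many
indicators cannot dominate. Orientation is chosen so that a larger index
means richer data, making the expected mortality relationship negative in
sign.

## The inequality metrics

Both metrics operate on fractional (ridit) ranks: units sorted worst-off
first (most data-poor / most deprived), each placed at the midpoint of its
cumulative weight share, tied units sharing their block midpoint. The
weighted mean of the ranks is exactly 0.5 by construction.

* **Relative concentration index**: RCI = 2·cov\_w(y, r)/μ, dimensionless,
  in (−1, 1) for non-negative outcomes; 0 for a flat outcome, negative
  when the outcome is concentrated at the worst-off end. If μ = 0 the
  index is defined as 0 with a warning (a uniformly zero outcome carries
  no gradient).
* **Slope index of inequality**: the outcome is regressed on the
  fractional rank by (weighted) least squares and the package reports
  SII = −β, the modelled gap *worst-off end minus best-off end*. This one
  convention is used everywhere: a mortality gradient against data
  availability yields positive SII with negative RCI, and a
  geocoding-success gradient against deprivation yields negative SII with
  positive RCI. Published tables in this literature are not always sign-
  consistent between those two cases, so the convention is stated here
  prominently; magnitudes are unaffected.

The default confidence interval is analytic: SII ∓ t₁₋α/₂,ₙ₋₂·SE(β) from
the WLS fit, the convention of the public-health toolkits that popularised
these metrics. A seeded percentile bootstrap (1 000 resamples by default,
ranks recomputed within each resample) is available via
`method = "bootstrap"` for small district sets where the t interval's
homoscedasticity assumption is doubtful. Degenerate inputs: a complete tie
in the ranking variable leaves the slope undefined and is a hard error;
an exact linear fit legitimately returns a zero-width interval.

Units are equally weighted by default — each country is one observation,
matching the country-count framing of international comparisons.
`weighting = "count"` (districts weighted by geocoding attempts, countries
by population) is available where unit sizes differ by orders of
magnitude; with district counts spanning 10–70 facilities, rates from the
smallest districts are noisy enough that the weighted variant is worth
reporting alongside.

## The district deprivation index

Census indicators are assigned to six domains (information access,
education, energy, employment, water and sanitation, living conditions).
Each indicator is oriented by an explicit ±1 sign so that larger means
more deprived — the orientation map is a required argument, because
census variables point both ways and a silent default would corrupt the
index — then standardised to a z-score across districts, averaged within
domain, and the six domain means summed. The standard deviation uses the
population form (divide by *m*); with ~25 districts the choice is visible
in the third decimal of a z-score and cancels entirely in rank-based use.
Totals are invariant to affine rescaling of any raw indicator and average
zero across districts by construction. An indicator with zero variance
across districts has no defined z-score and is rejected by name rather
than silently dropped.

External development scores (e.g. district league tables, where higher
means *less* deprived) enter the same machinery through
`direction = "higher_less_deprived"`.

## Outlier diagnostics

Mortality is log-transformed (natural log; the base only rescales
coefficients, not studentised residuals or the outlier set, since the
screen is two-sided on |t|) and regressed on the overall index. Outliers
are countries with externally studentised residuals — each residual scaled
by the regression error re-estimated without that country — beyond 2 in
absolute value. Two numerical guards: when the residual standard error is
at floating-point noise (an exact fit), all studentised residuals are set
to 0; when only the leave-one-out variance degenerates (one extreme point
against otherwise exact data), the offending residual is ±∞ and is
flagged at any finite threshold.

## What the synthetic generator emulates

`simulate_countries()` draws a latent "data richness" *L* ~ Uniform(0,1)
per country and derives everything from it:

* Each ordinal indicator bins a noisy signal ρ·L + (1−ρ)·U by rank into
  the indicator's level set, with bin widths proportional to the
  catalog's reference counts — so at n = 183 the simulated marginal level
  distribution equals the reference distribution exactly, ties included.
  The fidelity ρ (default 0.9) controls how discordant providers are with
  one another.
* Travel-composite components use the same binning; walking and driving
  directions default to universal good coverage, as their reference
  counts record.
* Mean population per areal unit is log-linear *decreasing* in the signal
  (calibrated to the reference median 130 000 and 5th/95th centiles
  411 / 23 801 400), with the provider absent in the most data-poor 20%
  of countries so the national-population fallback path is exercised.
* Mortality is exp(a − b·L + ε), ε ~ N(0, σ²), σ = 0.15. Default
  gradients b: all-cause 1.0, communicable/maternal/perinatal/nutritional
  3.0, non-communicable 0.45, injuries 1.0 — communicable mortality spans
  a ~20-fold range across the digital divide while NCD mortality is
  comparatively flat, reproducing the qualitative cause-specific ordering
  the pipeline should detect. Baselines put rates on a per-100 000 scale
  (all-cause ≈ 1 300 at the data-poor end).
* GDP per capita and internet use rise with L (log-linear and logistic
  respectively); GDP is missing for 9 countries by default, so
  pairwise-complete correlation counts differ by covariate.

`simulate_districts()` uses a one-factor model: latent deprivation
D ~ N(0,1); twelve census indicators (two per domain, loading 0.8,
orientations alternating so the orientation map is genuinely exercised);
geocoding attempts uniform in 10–70 per district; successes binomial with
log-odds −0.5 − 0.5·D (success probability falling with deprivation,
around 40% on average); and an external development score equal to
60 − 12·D plus noise.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring countries or districts, heterogeneous facility types with
different geocoding difficulty, provider behaviour correlated with
anything other than the single latent, or measurement error in mortality
itself. Passing tests therefore demonstrate that the pipeline recovers
gradients from data with this latent structure — not that real coverage
tables satisfy it.

All randomness flows from one explicit seed argument; no global state is
consulted or mutated (`withr::with_seed` restores the RNG).

## Problem sizes and test design

The test suite exercises the analysis at its natural scale: replicate
calibrations use 200 simulated studies of 183 countries (null-gradient
mean |RCI| and SII sign recovery) and 100 studies of 25 districts
(deprivation-recovery correlation); the whole suite runs in about a
minute. Closed-form agreement between the covariance and summation forms
of the RCI is checked to 1e−12 on tie-free inputs, and rank aggregation is
checked against an exhaustive pairwise-comparison oracle for all instances
with up to 8 units and 4 indicators.

## Limitations

* Indicator granularity bounds the measurable inequality: a two-level
  indicator cannot produce as large an |RCI| as a continuous one, so
  cross-indicator comparisons of magnitude partly reflect level-set
  resolution.
* Provider coverage statements are taken at face value; affordability,
  licensing and export restrictions are invisible to the index.
* With ~20–25 districts, SII confidence intervals are wide and sensitive
  to single districts with few facilities; the count-weighted variant and
  the bootstrap interval are the recommended sensitivity analyses.
* The composite index weights indicators equally within domains by
  construction; no model-based (e.g. principal-component) alternative is
  provided.
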