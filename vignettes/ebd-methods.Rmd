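---
title: "Methods: probabilistic environmental burden of disease estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic environmental burden of disease estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebdpaf)
```

## The model

`ebdpaf` implements a comparative risk assessment for a national
population: for each combination of exposure route and pollutant it
estimates the *population attributable fraction* (PAF), the proportion of
an observed health burden that would disappear if exposure were reduced
to a counterfactual level, and applies it to baseline counts of deaths
and health-care-facility visits.

For a discrete exposure distribution the PAF is

$$
PAF \;=\;
\frac{\sum_x P(x)\,RR(x) \;-\; \sum_x P'(x)\,RR(x)}
     {\sum_x P(x)\,RR(x)},
$$

where $P(x)$ is the observed exposure distribution, $P'(x)$ the
counterfactual distribution, and $RR(x)$ the relative risk at exposure
level $x$ (the reference category carries $RR = 1$). With the default
all-in-reference counterfactual this reduces to the familiar
$\sum_x p_x (RR_x - 1) \,/\, (1 + \sum_x p_x (RR_x - 1))$, which
`paf_categorical()` implements and the test suite verifies algebraically.
For continuous exposures the sums become integrals, which
`paf_continuous()` evaluates by deterministic quadrature.

Pollutants that act independently on the same endpoint within a route
(e.g. second-hand smoke and incense smoke on lung cancer; mold and
second-hand smoke on childhood asthma) are merged multiplicatively:

$$ PAF = 1 - \prod_i (1 - PAF_i), $$

and the attributable count is $D_{attrib} = PAF \times D_{total}$ with
the observed baseline $D_{total}$. Routes are always estimated
separately — gastroenteritis appears independently under the
drinking-water and coastal-water routes, and route PAFs are never
combined across routes.

The counterfactual is the elimination of pollution to background: zero
for all routes except outdoor air, where background concentrations are
uniform distributions — (5, 35) µg/m³ for PM~2.5~, (10, 90) µg/m³ for
PM~10~ and (0, 25) ppb for ozone — drawn once per iteration as a national
policy level rather than per cell.

## Uncertainty propagation

Every uncertain input is a declarative `dist_spec` (point, uniform,
triangular, lognormal, normal, Bernoulli, with optional lower
truncation). Published relative risks given as a central estimate with a
95% CI become lognormals anchored at the **median**
(`meanlog = log(central)`, `sdlog = log(ucl/lcl)/3.92`); anchoring at the
median preserves the printed point estimate under the log transform, and
when the printed CI is asymmetric only the upper/lower *ratio* enters the
single spread parameter. Whether the original implementation anchored
the mean or the median is not documented anywhere we could check; the
median convention is a deliberate design choice here, and the
reproduction tests pass under it. Exposure surveys reported as an
arithmetic mean and SD become moment-matched lognormals.

Sampling uses a Latin hypercube: for each input the unit interval is
split into $n$ equiprobable strata, one uniform sub-draw is taken per
stratum, and the stratum order is permuted independently per variable
before inverse-CDF transformation. Two implementation choices matter in
practice:

* **Substreams.** Each variable consumes its own random substream,
  derived deterministically from the root seed and the variable's name.
  Adding or removing a risk pair therefore never perturbs the draws of
  any other pair, which keeps results stable as scenarios evolve.
* **Truncation.** Truncated specs are sampled by inverse CDF on the
  truncated support (probabilities remapped onto $[F(a), 1]$), not by
  rejection, so stratification survives truncation exactly.

The default is 1,000 iterations, at which the drinking-water mean PAF is
stable to well under one standard error (`analysis/03_validation.R`
measures both the convergence and the ~90% seed-to-seed variance
reduction that stratification buys over simple random sampling).

Reported central estimates are the **mean** of the draws, and 95%
intervals are the 2.5th/97.5th percentiles under the
linear-interpolation quantile convention (R type 7), fixed so intervals
reproduce bit-identically. Display rounding (three significant figures
above 10,000, nearest 10 between 1,000 and 9,999, integers below, one
decimal on percentage fractions) matches the precision pattern of
national burden tables; raw values are always retained.

## Variability versus uncertainty

Within one Monte Carlo iteration, *parameter uncertainty* (relative
risks, prevalences, background levels) is sampled, while *across-person
variability* in continuous exposure (household radon and formaldehyde
concentrations, per-cell outdoor concentrations) is integrated out by
quadrature on 512 equiprobable quantile points. This split follows the
standard risk-analysis treatment of uncertainty versus variability; the
source material does not state the split explicitly, so it is a design
choice of this package, cross-checked against brute-force sampling
oracles in the tests.

Two floors implement the "no protective effect" rule: per-unit relative
risks are floored at 1 whenever exposure is at or below the
counterfactual (the counterfactual is clean background, not an optimum),
and single-pollutant PAF draws that come out negative (possible when a
sampled RR falls below 1, e.g. the male nonsmoker lung-cancer RR with CI
0.6–1.8) are floored at zero before combination and attribution, keeping
count draws inside $[0, D_{total}]$.

## Route encodings and assumptions

The bundled `uae_2008.yaml` encodes 39 risk pairs across six routes.
Choices that go beyond the printed parameter tables, made once and not
revisited:

* **Sex-specific RRs** are mixed by a male share of 0.5 when no
  endpoint-specific split is available (no sex-resolved baselines are
  printed).
* **Coastal water.** Monthly beach enterococci concentrations are
  uniforms between the observed monthly extremes; the dose response is
  RR 1.34 per log10 with a floor of 1 organism/100 ml (months observed
  at zero would otherwise map to $-\infty$). Monthly PAFs get equal
  weights (an equal share of the annual gastroenteritis baseline per
  month). Swimming prevalence is population-weighted from the surveyed
  strata: citizen prevalences by age/sex with an assumed citizen age
  ≤ 14 share of 0.35 and a 50/50 sex split, noncitizens at 6.2%, and an
  81% noncitizen population share — giving 5.3% overall. The Dubai
  population share (exposed to doubled concentrations after the
  wastewater overflows) is set to 0.30.
* **Radon** exposure data cover Abu Dhabi city and Sharjah only; the
  pairs carry a mixture exposure (lognormal and triangular components,
  weights 0.55/0.45) applied to 45% of the national baseline, are
  flagged `report_separately`, and never enter route totals. The printed
  radon CI (1.13, 1.16) cannot bracket its central estimate 1.08; the
  scenario encodes the source study's interval (1.03, 1.16).
* **Mesothelioma** is attributed at 100% of observed cases for deaths
  and at the sex-specific 90%/25% rule on an (all-male) visit baseline —
  the two attribution rules that reproduce the respective published
  rows; both are available in `fixed_fraction_attribution()`.
* **Occupational leukemia and lung cancer** keep their published
  two-level RRs, but the exposed-workforce fractions are unpublished;
  the config carries clearly marked placeholders and those rows are
  excluded from reproduction tests. Occupational asthma and COPD are
  omitted entirely (occupation-specific RRs live in an external
  workforce analysis).
* **Second-hand smoke** RRs are for nonsmokers but are applied to the
  whole endpoint baseline (no smoking-status stratum), which is the
  configuration that reproduces the published cardiovascular fraction.

## Known discrepancies

Reproduction checks are deliberately not asserted for rows the published
tables themselves render ambiguous: the climate-change cardiovascular
*visits* row (printed fraction 0.2% is inconsistent with the printed RR
of 1.001, which yields ~0.1%; the deaths row reproduces exactly), the
drinking-water gastroenteritis *deaths* row (printed fraction 12.8% is
inconsistent with its own printed counts 4 of 7), and the formaldehyde
asthma row (per-person integration of the heavy-tailed concentration
distribution gives about three times the printed 74 visits; a
population-mean-RR reading gives ~90, and which form was used is
unclear — the pair is reported separately, as in the original).

## Synthetic data: what it does and does not show

The synthetic generators exist so every stage runs and is tested without
any undeposited input. `generate_grid()` emulates the 1,164-cell
national concentration grid with a log-uniform population allocation
(dense cities, sparse desert) and uniform-range concentration
parameters; `generate_known_paf_scenario()` inverts the PAF closed forms
so the full pipeline can be checked against exact ground truth; and
`generate_baseline_health()` builds stratified baselines in a
deterministic expected-count mode by default (binomial noise is opt-in)
so recovery checks are sharp.

What passing these tests shows: the sampling, integration, combination
and attribution machinery is correct to its closed forms and oracles.
What it does not show: anything about the real spatial structure of
outdoor-air exposure. The original grid was interpolated from monitor
data and is unpublished, so outdoor-air results here characterize
synthetic grids only and the published outdoor-air numbers (651 deaths,
7.3%) are not reproduction targets. Cell draws are independent across
cells by default; `generate_grid(spatial_corr = TRUE)` adds
exponential-kernel autocorrelation for robustness probes, which leaves
the population-weighted mean unchanged but widens intervals.

## Problem sizes

The bundled scenario (39 pairs, 1,000 iterations, 512 quadrature points,
1,164-cell synthetic grid) completes in a few seconds on one core; the
test suite uses 50–2,000 iterations and up to 4,096 quadrature or oracle
points per check, sizes at which every Monte Carlo comparison has at
least three standard errors of headroom.
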