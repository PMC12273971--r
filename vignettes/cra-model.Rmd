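---
title: "Modelling health-expenditure savings from NCD risk-factor reductions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling health-expenditure savings from NCD risk-factor reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ncdcra` implements a deterministic comparative risk assessment (CRA) that
translates counterfactual reductions in the prevalence of four
noncommunicable-disease risk factors — tobacco use, harmful alcohol use, high
systolic blood pressure and high blood glucose — into (a) savings in
projected current health expenditure (CHE) and (b) percent reductions in
disability-adjusted life years (DALYs), for five conditions: cancer
(neoplasms), type 2 diabetes mellitus, cardiovascular disease (CVD), chronic
obstructive pulmonary disease (COPD) and chronic kidney disease (CKD).

The annual policy impact for country $i$, age group $j$, condition $k$ and
risk factor $p$ in year $t$ is the product

$$
P_{ijkpt} \;=\; \mathrm{CHE}_{ij v(k) t}\;\times\;\mathrm{Share}_{k}
\;\times\; \Delta_{p}\;\times\;\mathrm{PAF}_{ijkpt}\;\times\; r(t),
$$

where $v(k)$ is the ICD-10 chapter housing condition $k$,
$\mathrm{Share}_k$ is the fixed fraction of that chapter's expenditure
attributable to the condition, $\Delta_p$ is the scenario's fractional
prevalence reduction for risk factor $p$, $\mathrm{PAF}$ is the population
attributable fraction (the ratio of attributable to total DALYs), and
$r(t)$ is a linear phase-in. Impacts are summed over age groups, reported
per (country, risk factor, condition, year), and discounted to present
value. Cumulative discounted savings per country and risk factor are also
expressed as a percentage of discounted cumulative base-case CHE over *all*
chapters.

Key structural assumptions, inherited from the model form:

* **Linearity in the reduction.** $P$ is proportional to $\Delta_p$, so a
  25% scenario is exactly five times a 5% scenario, cell by cell.
* **Additivity across risk factors.** A joint scenario is the cellwise sum
  of the single-factor scenarios; there is no interaction term. This is
  what makes a "combined" column equal to the sum of its per-factor
  columns.
* **One lag for everything.** A risk-factor change feeds through to
  condition prevalence over a single linear ramp (10 years by default),
  identical for every condition; disease-specific lag structures are out of
  scope.
* **No uncertainty.** All quantities are deterministic point estimates; the
  package produces no intervals.

### Evaluation-year convention

The impact equation indexes the left side a decade after the factors on the
right. We evaluate every factor — expenditure, PAF, ramp, discount — at the
impact year itself; the phase-in ramp is what carries the ten-year lag. The
alternative reading (PAF frozen at the adoption year) coincides with ours
whenever PAFs are time-constant, which is the generator's default and the
least-assumption choice given that no within-horizon PAF dynamics are
specified.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `reductions` | — | fraction of prevalence | one per risk factor; 0.05/0.10/0.25 are the canonical scenarios |
| `start_year` | 2020 | year | ramp is 0 here: effects accrue from the following year |
| `ramp_years` | 10 | years | full effect at `start_year + ramp_years`, persisting through the horizon |
| `horizon_end` | 2050 | year | accounting window is `start_year..horizon_end` inclusive |
| `discount_rate` | 0.03 | per annum | end-of-year convention, exponent `year - base_year` |
| `base_year` | `start_year` | year | discount anchor; the base year is undiscounted |
| condition shares | 1, 0.2485, 0.9191, 0.3689, 0.372 | fraction of chapter CHE | cancer, diabetes, CVD, COPD, CKD; single national values applied to all ages and countries |

The ramp anchor and the discount base year are configurable because the
source accounting window (2020–2050) does not pin them down uniquely; the
defaults reach full effect in 2030 and discount to 2020. The
percent-of-cumulative denominator uses *discounted* base-case CHE so the
statistic is unit-free and invariant to a common currency rescaling — a
property the test suite asserts; an undiscounted denominator is available
via `discount_denominator = FALSE`.

Condition shares carry an optional age dimension in principle, but only a
single national value per condition is available, so the default applies
that value to every age group. Negative reductions (prevalence increases)
are accepted and produce negative savings, reported as added expenditure.

### DALY averaging

`daly_reduction()` computes, per condition, risk factor and reduction level
$s$: within each country the DALY-weighted mean PAF across age groups
(evaluated at a full-ramp year), times $s \times 100$; then the unweighted
mean across countries. "Average over countries" is read as an unweighted
mean; a DALY-weighted cross-country mean is available via
`country_weighting = "daly_weighted"`. Countries with zero total DALYs for
a condition are excluded from that condition's average with a warning.
Under PAFs that are uniform across countries and ages the statistic
collapses to the exact product $s \times \mathrm{PAF} \times 100$, which is
what the worked-example tests pin down.

## The synthetic generator

`generate_inputs()` emulates the joint structure of the three inputs the
CRA needs — none of which is redistributable at the required granularity —
for 16 Latin American and 8 Caribbean countries by default:

* **Expenditure**: 21 ICD-10 chapters × 18 five-year age bands (0–4 … 85+)
  × 2020–2050, strictly positive, with smooth compound growth per
  (country, chapter) drawn around 4% ± 1% per annum. Country magnitudes are
  drawn per expenditure group (four groups by per-capita spending, cycled
  within region), with the five condition-bearing chapters given realistic
  shares of national expenditure and steeply age-increasing profiles.
* **PAFs**: drawn per country uniformly inside per-pair ranges centred on
  the regional mean fractions back-solved from the published percent DALY
  reductions (e.g. tobacco→COPD ≈ 0.458, hypertension→CVD ≈ 0.523,
  glucose→diabetes fixed at 1 since diabetes is fully attributable to high
  blood glucose by definition), ±10% relative width, exactly zero on the
  twelve-cell link matrix's complement. Time-constant by default, with
  optional drift and age-gradient knobs (off by default: no within-horizon
  PAF dynamics or age gradients are specified by the source, so constancy
  is the least-assumption choice).
* **DALYs**: positive, heavier at older ages, scaled per country with the
  same expenditure-group structure.

Each (dataset, country) pair has its own random stream seeded from the
master seed and the country *code*, so adding a country never perturbs
another country's draws and a fixed seed yields byte-identical CSVs.

What the generator does **not** emulate: real country identities or
magnitudes, demographic projection, between-age PAF gradients estimated
from data, comorbidity structure, or any COVID-era disruption. Passing
tests on synthetic inputs therefore demonstrates the *arithmetic* of the
model — linearity, additivity, discounting, aggregation — and the
pipeline's determinism, not the empirical accuracy of any country estimate.
`calibrate_to_totals()` closes part of that gap for validation purposes: by
linearity, scaling each risk factor's impact by one multiplicative factor
reproduces any set of nonnegative per-factor cumulative totals, and the
joint scenario then reproduces their sum exactly (additivity), which is how
the suite reconstructs the published all-country combined total.

## The baseline projection

When only a base-year expenditure snapshot is available,
`project_che()` supplies the counterfactual via the multiplicative
recurrence

$$
\mathrm{CHE}_t = \mathrm{CHE}_{t-1}\,(1+\mathrm{pop}_t)\,(1+\mathrm{prev}_t)\,(1+\mathrm{res}_t),
$$

with discrete annual compounding and the three growth components
(population change, disease-prevalence change, and a composite residual
capturing technology, wages and coverage) supplied as exogenous inputs.
Whether the source projections compound these factors multiplicatively or
additively is not stated; we implement the multiplicative form (the natural
reading of a recurrence on the previous year's level) and flag it here.
Chapter XXI (factors influencing health status) has no meaningful
prevalence trend and its prevalence factor is held flat at zero. Users with
a full external projection bypass this module entirely.

## Numerical choices

* All arithmetic is double precision; rounding (savings to integer
  millions, percents to two decimals) happens only at rendering.
* Aggregation before rounding: region subtotals and grand totals are sums
  of unrounded member cells, so a displayed subtotal may differ from the
  sum of displayed rows by one unit in the last place per member.
* The ramp is clamped to $[0,1]$; a zero-length ramp is a step the year
  after adoption. With annual compounding over `start..end` inclusive, the
  ramp's total shortfall on constant inputs is exactly
  $(\texttt{ramp\_years}+1)/2$ annual full-effect amounts (the
  continuous-time value would be $\texttt{ramp\_years}/2$); the suite
  asserts the discrete closed form against a year-loop oracle.
* Validation is front-loaded: series constructors reject negative values,
  out-of-range fractions, nonzero PAFs on unlinked pairs, duplicate keys
  and year gaps, naming the offending cell, so the engine can assume clean
  inputs.
* Degenerate inputs: an empty horizon is an error; zero total DALYs for a
  (country, condition) excludes the country from that average with a
  warning rather than propagating `NaN`.

## Problem sizes used in tests

The unit and property tests run on 2–5 synthetic countries (a few seconds
in total); the end-to-end determinism check runs the full default 24
countries × 18 age bands × 21 chapters × 31 years twice. The acceptance
script regenerates the full-scale synthetic set and recomputes the four
worked DALY-reduction cells, which are exact products independent of the
random draws.

## Known limitations

* Condition shares within chapters come from a single country's
  administrative data and are applied everywhere; where national cost
  structures differ (e.g. a large Chagas burden inside the circulatory
  chapter), condition-level savings will be biased accordingly.
* Savings are gross: no implementation or upfront intervention costs, and
  no indirect (productivity, human-capital) effects.
* Only four risk factors and five conditions are covered, so the totals
  are a conservative lower bound on the expenditure linked to these risk
  factors.
* The single linear lag ignores cumulative exposure and condition-specific
  latency (e.g. lung cancer responds to tobacco cessation much more slowly
  than a decade).
* DALY reductions are not monetised.
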