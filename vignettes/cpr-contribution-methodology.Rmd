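---
title: "Modelling an organisation's contribution to increasing the modern CPR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an organisation's contribution to increasing the modern CPR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpimpact)
```

## The problem

The modern contraceptive prevalence rate (CPR) — the proportion of women of
reproductive age (WRA, 15–49) using a modern method — is the standard metric
for family planning programmes, but a single service delivery organisation
cannot read its contribution to the CPR off its own service statistics. Two
effects intervene:

* **Continuation.** A woman fitted with an IUD or implant, or sterilised, is
  a user for many years after the single year in which a service was
  recorded. Annual service counts (and couple-years of protection, which sum
  future protection over an undefined period) cannot be annualised into
  users-in-a-given-year.
* **Substitution.** Some "new" clients were already using contraception from
  another provider. They inflate the organisation's numbers without moving
  the national CPR at all.

`fpimpact` implements the level-1 accounting of Marie Stopes International's
Impact 2 model: it converts yearly commodity/service counts into modelled
user numbers, then decomposes those users into the part that maintains the
organisation's previous contribution (including the extra users needed just
to keep pace with population growth) and the part that genuinely increases
the national CPR, expressed in percentage points of (all or in-union) WRA.

## From services to users

**Long-acting methods** (IUDs, implants). Services provided in year $y$
create a virtual cohort. With $CCR_n$ the cumulative continuation rate $n$
years after insertion ($CCR_0 = 1$),

$$\mathrm{Users}_{m,y+n} = \mathrm{Services}_{m,y}\cdot
  \tfrac{1}{2}\left(CCR_n + CCR_{n+1}\right),
  \qquad n = 0,\dots,D_m - 1,$$

and the whole cohort is removed at the method's maximum duration $D_m$.
Averaging adjacent rates credits mid-year discontinuers with half a year of
use. Mortality is deliberately *not* applied to these cohorts — the CCR
tables already describe net attrition of use. When a supplied table lacks
the terminal entry $CCR_{D_m}$ it is taken as 0, consistent with removal.

**Permanent methods** (sterilisation). The cohort is thinned only by
mortality, applied recursively year on year:

$$\mathrm{Users}_{y+n} = \mathrm{Users}_{y+n-1}\cdot
  \left({}_5p_x\right)^{1/5},$$

where ${}_5p_x$ is the five-year survival probability for the age group
containing the cohort's median age (starting at the median age of
sterilisation and ageing one year per year), taken from the country's
assigned model life-table family at the life expectancy $e_0$ projected for
calendar year $y+n$. The fifth root converts five-year survival to annual
survival under an even-distribution assumption. The printed one-step form
of this equation can be read as non-cumulative; this package follows the
recursive description, under which survival compounds over the cohort's
life, and treats that as the intended semantics. The cohort is removed in
the first year its median age exceeds 49 (ages 15–49 inclusive count as
reproductive age). For male sterilisation the protected female partner is
the counted user; absent partner-age data, her age is taken at the same
median age of sterilisation — a documented simplification, not an estimate.

**Short-term methods** (pills, injectables, condoms) confer no protection
beyond the year, so

$$\mathrm{Users}_{m,y} = \mathrm{Services}_{m,y} /
  \mathrm{UnitsPerYear}_m,$$

with e.g. 13 pill cycles per covered user-year. This is conservative: 13
cycles are one fully covered user, never 13 part-year users. Fractional
users are kept throughout; rounding to whole women happens only in report
rendering, so the iterative engine accumulates no rounding bias.

**Condoms** are excluded from CPR accounting by default (a toggle): wastage
and dual protection make condom user estimates the least reliable.

## From users to percentage points of CPR

For a trend $y_1 \dots y_n$ measured against baseline year $y_0 = y_1 - 1$,
each year is processed as:

1. **Baseline**: total modelled users in $y_0$ (cohorts from the whole
   history, which may reach back to 1982) over the $y_0$ denominator.
2. **Pre-existing users**: users in the current year from LAPM cohorts
   provided at or before $y_0$. They were credited at baseline and count in
   full.
3. **New users**: this year's services converted to first-year users
   (long-acting discounted by $\tfrac12(CCR_0 + CCR_1)$, sterilisations by
   one year of survival, short-term by units-per-year).
4. **Allocation**: with the client profile splitting new users into
   continuers $C$, adopters $A$ and provider changers, and
   $\mathrm{needed} = \max(0,\ \mathrm{total}_{y-1} - \mathrm{pre} -
   \mathrm{existing})$:
   * $C \ge \mathrm{needed}$: maintain $=\mathrm{needed}$, increase $=A$
     (surplus continuers are dropped from the count and surfaced as a
     diagnostic);
   * $C + A \le \mathrm{needed}$: maintain $=C+A$, increase $=0$;
   * otherwise: maintain $=\mathrm{needed}$, increase
     $=A - (\mathrm{needed} - C)$.
   Provider changers are never allocated — they are the substitution
   effect.
5. **Counting fraction**: $(\mathrm{maintain} + \mathrm{increase}) /
   \mathrm{new}$ (0 when there are no new users), applied uniformly across
   methods within the year.
6. **Existing users**: counted LAPM sub-cohorts continue into later trend
   years. Because every cohort formula is linear in services, the counted
   sub-cohort is the full trajectory scaled by the counting fraction; the
   provision year itself contributes nothing (those users are "new").
7. **Iteration**: each year measures against the year immediately before
   it, not against $y_0$; total users in CPR $=$ pre-existing $+$ existing
   $+$ maintain $+$ increase, an exact identity the tests assert.
8. **Output**: total users in CPR over the year's denominator, minus the
   baseline contribution, gives the percentage points of CPR increase. The
   denominator grows with WRA, which is precisely how population-growth
   offsets bind; the final year's value is the cumulative increase.

The clamp in step 4 is a deliberate choice for the case the original
description leaves open (carried-over users exceeding last year's total):
nothing needs maintaining, and the surplus still counts because it was
counted the year before.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `units_per_year` (pill / injectable / condom) | units per user-year | 13 / 4 / 120 | standard units-needed-for-one-year-of-coverage values; failure rates are deliberately not folded in |
| CCR tables | probability per year offset | bundled synthetic tables | placeholders with realistic monotone shape; replace with nationally applicable tables, which are revised regularly |
| `max_duration` | years | 10/5 (IUDs), 5/4/3 (implants) | device lifetimes |
| `median_age_sterilisation` | years | 32 | typical of survey-based national estimates; drives the survival ages |
| `cpr_basis` | — | `all-women` | must match the survey basis of the national CPR you compare against |
| life-table family + `e0` series | — | bundled synthetic two-family table | selects mortality for sterilisation cohorts; supply the country's assigned family |
| `exclude` | method names | `condom` | see above |
| trend window | calendar years | any contiguous range with history and demography; conventionally 2001–2020 | annual resolution, integer years only |

## The synthetic-data generator

`fixture_params()` / `generate_service_history()` /
`generate_assumption_set()` produce seeded, reproducible inputs with the
same structure as real ones: a years × methods units table (with
pre-baseline years so pre-existing cohorts exist), monotone CCR tables, a
growing WRA series with a linearly rising `e0`, and a compact two-level
life table. Defaults sketch a mid-sized programme in a high-fertility
setting: services growing ~20% a year with mild lognormal noise, five
million WRA growing 2.5% a year, about half of clients continuers. The
generator emulates *structure*, not any country: service mixes are
stationary up to a single growth rate, the client profile is constant,
demography is smooth, and reporting noise, stockouts, method switching and
age structure of clients are absent. Tests passing on generated data
therefore validate the accounting, not the realism of any particular
input; real analyses must bring real service data, demography and CCR
tables. `toy_example()` fixes one such input set (15 years, 1/100 scale,
the published 22.4/49.2/28.4 client profile) as a regression snapshot.

## Numerical choices and degenerate inputs

* Life-table lookups interpolate linearly in `e0` between anchor levels and
  clamp outside the anchor range; `e0` between demography years is linear
  in calendar year. Ages outside the covered groups, and demography gaps
  within the modelled horizon, are errors naming the year or age rather
  than silent extrapolations.
* Cohort matrices are built to an explicit horizon (default: the last
  demography year); truncation beyond the horizon cannot affect reported
  years.
* Zero-service trend years run normally: zero new users, allocation
  degenerates to situation 2, counting fraction 0.
* A single-year client profile is broadcast to all trend years with a
  warning (the standard proxy when only one exit-interview survey exists).
* Missing (year, method) cells are zero services; duplicate cells are an
  error, not a sum, in the constructor — the CSV reader reports the row.
* User counts are non-negative reals throughout; `users_needed_to_maintain`
  clamps at zero.

## Problem sizes in the test suite

The property suites run the full engine against an independently coded
straight-line reference on 100 random fixtures of 6–10 history years and
six methods, plus targeted fixtures for linearity, steady states,
adopter-share monotonicity and cohort removal; the whole suite completes in
well under a minute. These sizes were chosen as the smallest at which every
code path (all three allocation situations, sterilisation ageing, horizon
truncation, both CPR bases) is exercised.

## Known limitations

* The model cannot see other providers: results read as a contribution to
  increasing CPR only if all other providers at least maintain their
  baseline contributions. Provider changers are assumed replaced by their
  former provider, and clients who leave are assumed to stop using
  contraception — both conservative.
* Short-term continuation is proxied by the client profile; the model
  assumes all short-term users discontinue at year end unless resupplied.
* No feedback from contraceptive use to fertility or the WRA projection.
* Method switching toward more effective methods carries no credit within
  the CPR metric.
* A single counting fraction applies to all methods within a year; there
  are no per-method client profiles.
* The bundled CCR tables, demography and life table are synthetic
  placeholders for demonstration; published country benchmarks (see
  `madagascar_benchmarks()`) cannot be reproduced without the
  organisation's own service history and country default assumptions.
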