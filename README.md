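# fpimpact

Estimate a family planning service delivery organisation's contribution to
increasing the national **modern contraceptive prevalence rate (CPR)** from
its own service statistics, implementing the level-1 methodology of Marie
Stopes International's **Impact 2** model.

Service counts and couple-years of protection (CYPs) cannot measure an
organisation's national impact: clients of long-acting and permanent
methods (LAPMs — IUDs, implants, sterilisation) keep using for years after
the one year in which a service was recorded, and some "new" clients were
already using contraception from another provider (the substitution
effect). `fpimpact` addresses both. It is written for monitoring and
evaluation teams at service delivery organisations, and for researchers
auditing such estimates.

## The model

**Users from services.** Long-acting services in year *y* create a virtual
cohort thinned by cumulative continuation rates (CCR):

    Users[m, y+n] = Services[m, y] × (CCR_n + CCR_{n+1}) / 2,   n = 0 … D−1,

with removal at the method's maximum duration *D*. Sterilisation cohorts
are thinned recursively by annualised life-table survival, `(₅pₓ)^(1/5)`,
at the cohort's median age, until the cohort ages past 49. Short-term
users are `services / units_per_year` (13 pill cycles = one user-year).
Summing all cohorts alive in a year plus that year's short-term users
gives modelled users per year.

**Percentage points of CPR.** Each trend year, new users split by the
client profile (% adopters / % continuers / % provider changers) are
allocated first to *maintaining* the previous year's total — including the
extra users required because the women-of-reproductive-age (WRA)
denominator grows — and only the remaining adopters *increase* the CPR.
Provider changers never count. Total users counting in CPR divided by WRA
(all or in-union), minus the baseline-year contribution, is the
organisation's percentage-point contribution to increasing the modern CPR.

## Worked example

```r
library(fpimpact)

ex <- toy_example()   # bundled 15-year synthetic programme, 1/100 scale
trend <- run_trend(ex$history, ex$assumptions, ex$profile,
                   y_start = 2005, y_end = 2010)
cat(summary_report(trend))
```

```
Contribution to increasing the modern CPR
==========================================
Baseline year 2004: 296 modelled users, 0.48% of WRA

year      pre-exist     existing     maintain     increase     in CPR  pp incr
2005            166            0          130           18        315     0.02
2006            131           56          128           58        373     0.09
...
2010             77          302          271          142        792     0.60

Cumulative contribution to increasing CPR, 2005-2010: 0.60 percentage points
```

Reading the 2006 row: 131 users remain from cohorts served up to the 2004
baseline (*pre-existing*), 56 continue from LAPM cohorts counted in 2005
(*existing*), 128 of 2006's new users fill the gap back up to 2005's total
(*maintain*), and 58 adopters push above it (*increase*) — together 373
users count in the CPR, 0.09 percentage points of WRA above the baseline
contribution. Only ~72% of each year's new users count at all
(`trend$years$counting_fraction`): the rest are provider changers, already
in the national CPR.

Other entry points: `profile_sweep()` re-runs the trend under alternative
client profiles (the standard low/actual/high adopter-share sensitivity),
`user_estimates()` tabulates modelled users alone, `cyp_total()` reports
conventional CYPs for comparison, and `generate_service_history()` /
`generate_assumption_set()` produce seeded synthetic inputs. A thin CLI
lives at `inst/cli/impact.R` (`run`, `sweep`, `fixture` subcommands over
YAML configs). Bundled reference data include the published Madagascar
2005–2011 user table (`madagascar_published_users()`) and its headline
benchmarks (`madagascar_benchmarks()`), which require the organisation's
full service history and country assumptions to recompute.

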