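---
title: "Estimating the mortality and productivity burden of HPV-attributable cancers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the mortality and productivity burden of HPV-attributable cancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpvburden)
```

## The question

HPV causes cancers at six sites — cervix, vagina, vulva, penis, anus and
oropharynx — and most of the causally relevant high-risk types (16, 18, 31,
33, 45, 52, 58) are covered by the nonavalent vaccine. `hpvburden`
estimates what deaths from those cancers cost society: how many deaths are
attributable to HPV (overall and by type group), how many years of
potential life they erase, and the present value of the market and
non-market productivity those years would have carried. These are the
standard outcome measures of human-capital burden-of-illness studies, and
they feed directly into cost-effectiveness evaluations of vaccination.

## The model, step by step

**Attribution.** Registry death counts arrive stratified by site, sex and
single year of age (15–100). Each (site, sex) stratum has a fixed fraction
of cancers attributable to any HPV, to HPV 16/18, and to HPV
31/33/45/52/58; the 9vHPV-targeted group is the sum of the latter two. The
fractions come from US genotyping surveys and are age-invariant, so
attribution is a scalar multiplication per stratum and the scaled counts
stay fractional — rounding happens only in report output. The packaged
fractions satisfy `f_1618 + f_5types <= f_any` row-wise, and the code
enforces that ordering on any table it reads, which makes the 9v results
automatically bounded by the any-HPV results.

**YPLL.** A death at age *a* loses `e(sex, a)` years, the sex-specific
remaining life expectancy read from a period life table; stratum YPLL is
the count-weighted sum. No discounting or age weighting is applied to
YPLL — it is a pure count of years.

**PVFLP.** Each death at age *a* forfeits one productive year at every
attained age `k = a + 1, ..., a + floor(e(sex, a))`; the year of death
itself is not counted. A year at attained age *k* is worth

* market: `participation(k) x weekly_wage(k) x 52 x markup`, and
* non-market: the annual value of household and caregiving work at age *k*,

both looked up in the age-bin x sex economic profile at the *attained* age,
so a woman dying at 25 is valued with the 25–29 bin for ages 26–29, the
30–34 bin thereafter, and so on; attained ages past 100 stay in the
terminal 75+ bin. Each year is discounted by `(1 + r)^-(k - a)`, so the
first lost year is discounted exactly once — deaths occur in the reference
year, and the first forfeited year is the one after. Market and non-market
streams are accumulated separately and reported separately and summed.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `discount_rate` | 0.03 | per year | the reference-case rate recommended for US health-economic evaluation |
| `markup` | 1.464 | — | converts wages to total compensation including employer-paid fringe benefits |
| `annualization` | `weeks52` | — | weekly wages × 52 gives annual earnings; see below |
| `first_lost_age_offset` | 1 | years | no productivity is counted in the year of death |
| `final_year_handling` | `truncate` | — | drop the fractional part of `e`; `fractional` weights one extra year by it |
| `reference_year` | 2017 | — | the mortality year; all dollars are 2017 USD |

The `as_printed` annualization mode exists because hand-worked examples of
this calculation are often quoted on the literal weekly-wage scale
(participation × weekly wage × markup, labelled "per year"). Headline
burden totals in the hundreds of thousands of dollars per death are only
attainable when weekly wages are annualized, so the pipeline default is
`weeks52` and `as_printed` is kept solely so that `worked_example()` can
verify the quoted arithmetic at its own scale. Both modes share every other
code path.

Truncation versus fractional weighting of the final year is genuinely
undecidable from the published record (the canonical worked example has an
integer life expectancy, on which the two agree), so both are implemented;
`truncate` is the default and the choice moves totals by well under one
year's value per death.

## Packaged inputs

* `attribution_us_2008_2010.csv` — attribution percentages per site (and
  per sex for the two-sex sites). Stored on the 0–100 scale as published;
  converted to fractions at the I/O boundary only.
* `econ_profile_us_2017.csv` — participation, median weekly wage and
  annual non-market value for fifteen age bins ({15}, [16,17], [18,19],
  [20,24], five-year bins to [70,74], [75,100]) per sex. The age-15 bin is
  zero-productivity: no participation data exist for it.
* `life_table_2016_synthetic.csv` — a **synthetic** life table: a monotone
  spline through period-life-table-like anchor knots, fixed so that
  e(female, 25) = 57.0 exactly, matching the worked example's anchor
  (published 2016 US tables give ≈ 56.8). It is representative in shape
  but is not an official table, and the file header says so.

Non-market values carry no participation or markup multiplier: they are
population-average annual amounts already built from time-use hours times
a replacement wage.

## The synthetic mortality generator

The age- and sex-stratified 2017 registry extract behind the published
burden tables was never deposited; only six per-site totals are public
(4,207 cervical; 411 vaginal; 1,262 vulvar; 352 penile; 1,169 anal; 1,154
oropharyngeal — 8,555 deaths). The generator emulates such an extract: for
each site it discretizes a truncated normal age-at-death distribution on
15–100 and allocates exactly the requested total multinomially across
(sex, age) cells, so per-site totals are conserved for every seed and the
same seed reproduces the same table byte-for-byte. An `expected` mode
returns the variance-free expected counts for deterministic tests.

Defaults were fixed once, before any results were inspected: the public
totals above; age modes set near published median ages at diagnosis plus a
modest survival lag (58 cervix, 70 vagina, 72 vulva, 71 penis, 64 anus, 63
oropharynx; spreads 12–15 years); and female shares 0.63 (anal) and 0.22
(oropharyngeal) for the two-sex sites, loosely back-calculated from the
relative attributable burden by sex. The shares and age parameters are
synthetic free parameters, not estimates: the true age structure and sex
splits are unpublished.

What passing tests therefore show: every *structural* property of the
analysis — attribution linearity, type-group additivity, conservation
across strata, discounting identities, oracle-verified per-year
accumulation — holds on data shaped like a registry extract, and the
deterministic anchors (worked example, single-sex-site attributable
totals) are reproduced exactly. What they do not show: agreement of
age-structure-dependent aggregates (total YPLL, total PVFLP, per-death
averages) with the published US figures, which would require the
unpublished extract. With the default profiles those aggregates do land on
the published scale — about 7,088 any-HPV deaths, ~165,000 YPLL, ~$4.4
billion PVFLP, ~$744K per cervical death, 91.2% of YPLL in the 9v group —
but only the scale, not the values, is meaningful, so the test suite
asserts order of magnitude and nothing tighter.

## Numerical choices

* Attribution multiplies exact counts; site totals are summed before any
  rounding, and report rounding is half-up at the final step (so a
  `x.5` cell rounds away from zero, matching standard tabulation).
* Counts, YPLL and PVFLP are all linear in the death counts, and the code
  keeps them that way: per-death quotients are totals divided by totals,
  flagged `NA` when a stratum has zero deaths rather than forced to zero.
* Life expectancy is used as read, possibly fractional; coverage of every
  single year 15–100 per sex is validated at read time so age lookups can
  never interpolate silently.
* Report CSVs write numbers at full `%.17g` precision next to the rounded
  presentation columns, so a read-back reproduces every stored value
  exactly and downstream consumers never re-round.
* The generator isolates its RNG: it seeds deterministically and restores
  the caller's random state afterwards.
* WONDER-style exports: the trailing provenance block (blank line or
  `---`) is discarded, rows with a non-empty `Notes` field (including
  `Total` rows) are dropped, the `100+` bucket maps to age 100, and
  suppressed counts abort the read with the offending rows listed —
  silently treating suppression as zero would bias every downstream total.
  The ICD-10 → site map is configurable because oropharyngeal extractions
  legitimately differ (all of C00–C14 versus subsets such as C01–02, C09,
  C14); the default maps the full range.

## Problem sizes

The test suite runs the full pipeline on complete synthetic extracts
(8,555 deaths, ~6 sites × 86 ages × 2 sexes), verifies the discounted
stream against an independently coded per-year loop on 1,000 random
(age, sex, rate) cases, and checks generator conservation across 100
random seeds; the whole suite completes in well under a minute.

## Limitations

Beyond the synthetic age structure, the method inherits the standard
human-capital caveats: average wages overstate losses if disease falls
disproportionately on lower-income groups; only post-mortality losses are
counted (no morbidity, caregiving or medical costs before death); no wage
growth, taxes or friction-cost alternative is modelled; and attribution
fractions from archived-tissue genotyping are applied age-invariantly to
deaths, although type distribution could differ by age or between incident
cases and deaths. Uncertainty intervals are out of scope: every reported
quantity is a point estimate conditional on its inputs.
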