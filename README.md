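# hpvburden

Mortality burden and lost-productivity costs of HPV-attributable cancers.

Human papillomavirus (HPV) causes cancers of the cervix, vagina, vulva,
penis, anus and oropharynx. `hpvburden` quantifies what premature deaths
from those cancers cost, for health economists and vaccine policy analysts:
it apportions registry death counts to HPV type groups, converts each death
into **years of potential life lost (YPLL)**, and values those years with
the **human-capital approach** as the **present value of future lost
productivity (PVFLP)**, stratified by cancer site, sex, and HPV type group
(any HPV; HPV 16/18; HPV 31/33/45/52/58; all seven 9vHPV-targeted types).

## The model

For a site–sex stratum with attribution fraction *f* and *d(a)* registry
deaths at age *a* (ages 15–100), attributable deaths are *f·d(a)*, carried
forward unrounded. With *e(s, a)* the sex-specific remaining life
expectancy at the age of death,

```
YPLL = Σ_a f · d(a) · e(s, a)
```

Each death at age *a* then loses the years *k = a+1, …, a+⌊e(s,a)⌋* (no
productivity is counted in the year of death). A year lived at attained age
*k* is worth the market value `p(k) · w(k) · 52 · m` — labor-force
participation × median weekly wage × 52 weeks × the fringe-benefit markup
*m* = 1.464 — plus the population-average annual value of non-market
household and caregiving work `h(k)`. Both streams are discounted to the
reference year (2017) at rate *r* = 3%/year:

```
PVFLP = Σ_a f · d(a) · Σ_k (1 + r)^-(k - a) · [ p(k)·w(k)·52·m  +  h(k) ]
```

Economic inputs are age-bin × sex lookups (packaged, 2017 USD); attained
ages beyond 100 use the terminal 75+ bin. An `as_printed` annualization
mode values earnings on the literal weekly-wage scale for verifying
hand-worked arithmetic, and a `fractional` mode weights the final partial
year of life expectancy instead of truncating it.

## Worked example

```r
library(hpvburden)
worked_example()
#>                          quantity computed reference pass
#> 1       attributable deaths at 25    5.460      5.46 TRUE
#> 2          YPLL from deaths at 25  311.220    311.22 TRUE
#> 3 annual lost earnings ages 26-29  809.791    809.79 TRUE
#> 4 annual lost earnings ages 30-34  789.652    789.65 TRUE
```

Six cervical cancer deaths at age 25 with 91% HPV attribution give 5.46
attributable deaths; each carries 57 remaining years, hence 311.22 YPLL;
and a 25-year-old woman's lost earnings on the weekly-wage scale are
0.764 × $724 × 1.464 = $809.79/year at ages 26–29, dropping to $789.65
when she ages into the 30–34 participation bin.

A full run on a synthetic registry extract (per-site totals are the public
2017 US counts; the age structure is simulated):

```r
mort <- generate_mortality(default_paper_profiles(), seed = 1)
att  <- read_attribution(hpvburden_extdata("attribution_us_2008_2010.csv"))
lt   <- read_life_table(hpvburden_extdata("life_table_2016_synthetic.csv"))
econ <- read_econ_profile(hpvburden_extdata("econ_profile_us_2017.csv"))
res  <- compute_burden(mort, att, lt, econ, pvflp_settings(), groups = c("any", "9v"))
res[res$hpv_group == "any", c("site", "sex", "deaths", "ypll", "pvflp_total",
                              "ypll_per_death", "pvflp_per_death")]
#>         site    sex deaths   ypll pvflp_total ypll_per_death pvflp_per_death
#> 1       anus female  690.1  15161   3.726e+08          21.97          540008
#> 2     cervix female 3811.5 103181   2.835e+09          27.07          743875
#> 3 oropharynx female  163.3   3575   8.647e+07          21.89          529497
#> 4     vagina female  308.2   5419   1.190e+08          17.58          386002
#> 5      vulva female  868.3  13627   2.803e+08          15.69          322825
#> 6       anus   male  375.2   7557   2.430e+08          20.14          647629
#> 7 oropharynx   male  648.7  13088   4.143e+08          20.18          638718
#> 8      penis   male  222.8   3386   9.443e+07          15.20          423793
#> 9      total    all 7088.1 164993   4.445e+09          23.28          627169
```

About 7,088 of the 8,555 deaths are attributable to any HPV, carrying
~165,000 YPLL and ~$4.4 billion in discounted lost productivity; cervical
cancer dominates (~$744K per death). `write_results()` exports these as
`deaths_ypll.csv` and `pvflp.csv` report tables, and `run_pipeline()` wraps
the whole flow (including YAML configuration and a checksummed run log). A
thin command-line wrapper lives at `inst/cli/hpvburden.R` with `compute`,
`simulate`, `worked-example` and `check-tables` subcommands.

Real WONDER exports are read with
`read_mortality(path, dialect = "wonder")`, which maps ICD-10 codes
(C53, C51, C52, C60, C21, C00–C14) to sites, folds the `100+` bucket into
age 100, discards the trailing notes block, and refuses suppressed counts.

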