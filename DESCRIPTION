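Package: hpvburden
Title: Mortality Burden and Lost Productivity of HPV-Attributable Cancers
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the mortality burden of cancers attributable to human
    papillomavirus (HPV) in the United States: HPV-attributable deaths by
    cancer site, sex and HPV type group; years of potential life lost (YPLL)
    from sex-specific remaining life expectancy at the age of death; and the
    present value of future lost productivity (PVFLP) under the human-capital
    approach, combining discounted market earnings (labor-force participation
    x wages x a fringe-benefit markup) with the value of non-market household
    and caregiving work. Includes readers for CDC WONDER-style mortality
    exports, packaged attribution and economic input tables, a synthetic
    age/sex-stratified mortality generator for fully reproducible runs, and
    Table-style report writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
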