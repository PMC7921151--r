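# Apportionment of raw death counts to HPV type groups. One fraction per
# (site, sex); attribution is age-invariant and the scaled counts are carried
# forward unrounded.

group_fraction <- function(attribution, group) {
  switch(group,
         any = attribution$f_any,
         `1618` = attribution$f_1618,
         `5types` = attribution$f_5types,
         `9v` = attribution$f_1618 + attribution$f_5types,
         all_deaths = rep(1, nrow(attribution)),
         stop("unknown HPV group: ", group, call. = FALSE))
}

#' Apportion deaths to an HPV type group
#'
#' Multiplies every death count by the attribution fraction for its
#' (site, sex) stratum. Groups: `"any"` (any HPV), `"1618"` (HPV 16/18),
#' `"5types"` (HPV 31/33/45/52/58), `"9v"` (all seven 9vHPV-targeted
#' high-risk types, i.e. the 16/18 and 5-type fractions summed), and
#' `"all_deaths"` (fraction 1; the unattributed registry counts).
#'
#' @param deaths A [mortality_table()].
#' @param attribution An [attribution_table()] covering every (site, sex)
#'   present in `deaths`.
#' @param group HPV type group, see above.
#' @return A [mortality_table()] with scaled (generally fractional) counts.
#' @examples
#' d <- mortality_table(data.frame(site = "cervix", sex = "female",
#'                                 age = 25, deaths = 6))
#' a <- attribution_table(data.frame(site = "cervix", sex = "female",
#'                                   f_any = 0.91, f_1618 = 0.662,
#'                                   f_5types = 0.147))
#' attribute_deaths(d, a, "any")$deaths  # 5.46
#' @export
attribute_deaths <- function(deaths, attribution,
                             group = c("any", "1618", "5types", "9v",
                                       "all_deaths")) {
  group <- match.arg(group)
  deaths <- validate_mortality_table(deaths)
  if (nrow(deaths) == 0L) return(deaths)
  frac <- group_fraction(attribution, group)
  i <- match(paste(deaths$site, deaths$sex),
             paste(attribution$site, attribution$sex))
  if (anyNA(i))
    stop("no attribution row for: ",
         paste(unique(paste(deaths$site, deaths$sex)[is.na(i)]),
               collapse = "; "), call. = FALSE)
  deaths$deaths <- deaths$deaths * frac[i]
  deaths
}

#' Total deaths per (site, sex) stratum
#'
#' Exact sums over ages; no rounding.
#'
#' @param deaths A [mortality_table()].
#' @return Data frame with columns `site`, `sex`, `deaths`.
#' @export
site_totals <- function(deaths) {
  deaths <- validate_mortality_table(deaths)
  if (nrow(deaths) == 0L)
    return(data.frame(site = character(0), sex = character(0),
                      deaths = numeric(0), stringsAsFactors = FALSE))
  out <- stats::aggregate(deaths ~ site + sex, data = deaths, FUN = sum)
  out[order(out$site, out$sex), , drop = FALSE]
}
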