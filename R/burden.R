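# The core burden math: years of potential life lost (YPLL) and the present
# value of future lost productivity (PVFLP, human-capital approach).
#
# For a death at age a with remaining life expectancy L = e(sex, a), the lost
# years are the attained ages k = a + 1, ..., a + floor(L) (optionally plus a
# fractional final year). Each lost year contributes the age- and
# sex-specific annual market value (participation x wage x markup, with the
# wage annualized over 52 weeks in pipeline runs) and the annual non-market
# value, discounted by (1 + r)^-(k - a) so that the first lost year is
# discounted once.

#' Settings for the PVFLP calculation
#'
#' @param annualization `"weeks52"` multiplies the weekly wage by 52 to get
#'   annual earnings (the pipeline default); `"as_printed"` uses
#'   participation x weekly wage x markup as a literal per-year amount and
#'   exists to verify hand-worked arithmetic on the weekly scale.
#' @param discount_rate Annual discount rate (fraction/year).
#' @param markup Fringe-benefit markup on wages.
#' @param first_lost_age_offset First lost year begins this many years after
#'   the age at death (default 1: no productivity is counted for the year of
#'   death itself).
#' @param final_year_handling `"truncate"` drops the fractional part of the
#'   remaining life expectancy; `"fractional"` adds one more year weighted by
#'   that fractional part.
#' @return A `pvflp_settings` list.
#' @export
pvflp_settings <- function(annualization = c("weeks52", "as_printed"),
                           discount_rate = 0.03, markup = 1.464,
                           first_lost_age_offset = 1L,
                           final_year_handling = c("truncate", "fractional")) {
  annualization <- match.arg(annualization)
  final_year_handling <- match.arg(final_year_handling)
  if (!is.finite(discount_rate) || discount_rate < 0)
    stop("discount_rate must be non-negative", call. = FALSE)
  if (!is.finite(markup) || markup <= 0)
    stop("markup must be positive", call. = FALSE)
  structure(list(annualization = annualization,
                 discount_rate = discount_rate, markup = markup,
                 first_lost_age_offset = as.integer(first_lost_age_offset),
                 final_year_handling = final_year_handling),
            class = "pvflp_settings")
}

#' Years of potential life lost for a single death
#'
#' The sex-specific remaining life expectancy at the age of death, exactly.
#'
#' @param age Age(s) at death, 15-100.
#' @param sex `"female"` or `"male"` (recycled).
#' @param lt A [life_table()].
#' @return Years (vectorized over `age`/`sex`).
#' @export
ypll_for_death <- function(age, sex, lt) {
  if (any(age < AGE_MIN | age > AGE_MAX))
    stop(sprintf("age outside [%d, %d]", AGE_MIN, AGE_MAX), call. = FALSE)
  life_expectancy(lt, sex, age)
}

#' Total YPLL per (site, sex) stratum
#'
#' Sum over ages of count(age) x e(sex, age).
#'
#' @param attributed A [mortality_table()] (typically already scaled by
#'   [attribute_deaths()]).
#' @param lt A [life_table()].
#' @return Data frame with columns `site`, `sex`, `ypll`.
#' @export
total_ypll <- function(attributed, lt) {
  attributed <- validate_mortality_table(attributed)
  if (nrow(attributed) == 0L)
    return(data.frame(site = character(0), sex = character(0),
                      ypll = numeric(0), stringsAsFactors = FALSE))
  attributed$ypll <- attributed$deaths *
    ypll_for_death(attributed$age, attributed$sex, lt)
  out <- stats::aggregate(ypll ~ site + sex, data = attributed, FUN = sum)
  out[order(out$site, out$sex), , drop = FALSE]
}

# index of the economic age bin for attained age k (k beyond 100 falls into
# the terminal 75+ bin); vectorized
econ_bin_index <- function(econ, sex, age) {
  age <- pmin(age, AGE_MAX)
  if (any(age < AGE_MIN)) stop("age below economic-profile coverage", call. = FALSE)
  out <- integer(length(age))
  for (s in unique(sex)) {
    rows <- which(econ$bins$sex == s)
    j <- findInterval(age[sex == s], econ$bins$age_lo[rows])
    out[sex == s] <- rows[j]
  }
  out
}

#' Annual market productivity value at an attained age
#'
#' Participation x weekly wage x markup, times 52 under `weeks52`
#' annualization. The age-15 bin is zero by construction.
#'
#' @inheritParams ypll_for_death
#' @param econ An [econ_profile()].
#' @param settings A [pvflp_settings()].
#' @return USD per year (vectorized).
#' @export
annual_market_value <- function(age, sex, econ, settings = pvflp_settings()) {
  i <- econ_bin_index(econ, sex, age)
  weeks <- if (settings$annualization == "weeks52") 52 else 1
  econ$bins$participation[i] * econ$bins$weekly_wage[i] * weeks *
    settings$markup
}

#' Annual non-market productivity value at an attained age
#'
#' The annual value of unpaid household and caregiving work for the age bin;
#' a population-average amount, so no participation or markup multiplier
#' applies.
#'
#' @inheritParams annual_market_value
#' @return USD per year (vectorized).
#' @export
annual_nonmarket_value <- function(age, sex, econ) {
  i <- econ_bin_index(econ, sex, age)
  econ$bins$nonmarket_annual[i]
}

#' Discounted lifetime productivity lost to a single death
#'
#' Walks the lost years k = age + offset, ..., age + floor(L), values each at
#' the attained age (ages beyond 100 use the terminal 75+ bin), discounts by
#' `(1 + r)^-(k - age)`, and returns the market and non-market sums
#' separately. With `final_year_handling = "fractional"`, one further year
#' weighted by the fractional part of L is added.
#'
#' @inheritParams annual_market_value
#' @param lt A [life_table()].
#' @return Named numeric vector `c(market = , nonmarket = )` in USD.
#' @export
pvflp_for_death <- function(age, sex, lt, econ, settings = pvflp_settings()) {
  stopifnot(length(age) == 1L, length(sex) == 1L)
  L <- life_expectancy(lt, sex, age)
  nfull <- floor(L)
  frac <- L - nfull
  first <- age + settings$first_lost_age_offset
  last <- age + nfull
  if (last < first && !(settings$final_year_handling == "fractional" && frac > 0))
    return(c(market = 0, nonmarket = 0))
  k <- if (last >= first) seq.int(first, last) else integer(0)
  w <- rep(1, length(k))
  if (settings$final_year_handling == "fractional" && frac > 0) {
    k <- c(k, last + 1L)
    w <- c(w, frac)
  }
  disc <- (1 + settings$discount_rate)^(-(k - age))
  mkt <- annual_market_value(k, rep(sex, length(k)), econ, settings)
  non <- annual_nonmarket_value(k, rep(sex, length(k)), econ)
  c(market = sum(w * disc * mkt), nonmarket = sum(w * disc * non))
}

#' Full burden of a mortality table
#'
#' Per (site, sex) stratum: total deaths, YPLL, and market/non-market/total
#' PVFLP, with per-death averages, plus a whole-population `total` row. The
#' per-death quotients are `NA` where a stratum has zero deaths.
#'
#' @inheritParams pvflp_for_death
#' @param attributed A [mortality_table()] (typically already scaled by
#'   [attribute_deaths()]).
#' @param hpv_group Label recorded in the result's `hpv_group` column.
#' @return A `burden_result` data frame.
#' @export
total_burden <- function(attributed, lt, econ, settings = pvflp_settings(),
                         hpv_group = "all_deaths") {
  attributed <- validate_mortality_table(attributed)
  empty <- data.frame(site = "total", sex = "all", hpv_group = hpv_group,
                      deaths = 0, ypll = 0, pvflp_market = 0,
                      pvflp_nonmarket = 0, pvflp_total = 0,
                      ypll_per_death = NA_real_, pvflp_per_death = NA_real_,
                      stringsAsFactors = FALSE)
  if (nrow(attributed) == 0L) {
    class(empty) <- c("burden_result", "data.frame")
    return(empty)
  }
  # value each unique (sex, age) once, then weight by counts
  ua <- unique(attributed[, c("sex", "age")])
  pv <- t(vapply(seq_len(nrow(ua)), function(i)
    pvflp_for_death(ua$age[i], ua$sex[i], lt, econ, settings), numeric(2)))
  ua$pv_market <- pv[, 1]; ua$pv_nonmarket <- pv[, 2]
  ua$ex <- ypll_for_death(ua$age, ua$sex, lt)
  m <- merge(attributed, ua, by = c("sex", "age"), sort = FALSE)
  m$ypll <- m$deaths * m$ex
  m$pvflp_market <- m$deaths * m$pv_market
  m$pvflp_nonmarket <- m$deaths * m$pv_nonmarket
  agg <- stats::aggregate(cbind(deaths, ypll, pvflp_market, pvflp_nonmarket)
                          ~ site + sex, data = m, FUN = sum)
  tot <- data.frame(site = "total", sex = "all",
                    deaths = sum(agg$deaths), ypll = sum(agg$ypll),
                    pvflp_market = sum(agg$pvflp_market),
                    pvflp_nonmarket = sum(agg$pvflp_nonmarket),
                    stringsAsFactors = FALSE)
  out <- rbind(agg[order(agg$sex, agg$site), ], tot)
  out$hpv_group <- hpv_group
  out$pvflp_total <- out$pvflp_market + out$pvflp_nonmarket
  out$ypll_per_death <- ifelse(out$deaths > 0, out$ypll / out$deaths, NA_real_)
  out$pvflp_per_death <- ifelse(out$deaths > 0, out$pvflp_total / out$deaths,
                                NA_real_)
  out <- out[, c("site", "sex", "hpv_group", "deaths", "ypll", "pvflp_market",
                 "pvflp_nonmarket", "pvflp_total", "ypll_per_death",
                 "pvflp_per_death")]
  rownames(out) <- NULL
  class(out) <- c("burden_result", "data.frame")
  out
}
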