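# Synthetic WONDER-like mortality generator. The published analysis used an
# age/sex-stratified registry extract that was never deposited; only the
# per-site totals are public. The generator reproduces those totals exactly
# and fills in the age structure from a discretized truncated-normal
# age-at-death model, so the whole pipeline runs and is testable offline.

#' Site profile for the synthetic mortality generator
#'
#' @param site Cancer site.
#' @param total_deaths Non-negative integer total for the site.
#' @param female_share Fraction of the site's deaths in females; forced to 1
#'   for cervix/vagina/vulva and 0 for penis.
#' @param age_mode Peak of the age-at-death distribution (years, 15-100).
#' @param age_spread Dispersion (standard deviation, years, > 0).
#' @return A `site_profile` list.
#' @export
site_profile <- function(site, total_deaths, female_share, age_mode,
                         age_spread) {
  if (!site %in% HPV_SITES)
    stop("unknown cancer site: ", site, call. = FALSE)
  if (total_deaths < 0 || total_deaths != round(total_deaths))
    stop("total_deaths must be a non-negative integer", call. = FALSE)
  if (female_share < 0 || female_share > 1)
    stop("female_share must lie in [0, 1]", call. = FALSE)
  if (site %in% FEMALE_ONLY_SITES && female_share != 1)
    stop("female_share must be 1 for site ", site, call. = FALSE)
  if (site %in% MALE_ONLY_SITES && female_share != 0)
    stop("female_share must be 0 for site ", site, call. = FALSE)
  if (age_mode < AGE_MIN || age_mode > AGE_MAX)
    stop("age_mode must lie in [15, 100]", call. = FALSE)
  if (age_spread <= 0) stop("age_spread must be positive", call. = FALSE)
  structure(list(site = site, total_deaths = as.integer(total_deaths),
                 female_share = female_share, age_mode = age_mode,
                 age_spread = age_spread),
            class = "site_profile")
}

#' Default site profiles matching the published 2017 US per-site totals
#'
#' Totals are the public WONDER-derived counts (4,207 cervical; 411 vaginal;
#' 1,262 vulvar; 352 penile; 1,169 anal; 1,154 oropharyngeal; 8,555 in all).
#' The female shares of the two-sex sites (0.63 anal, 0.22 oropharyngeal)
#' and the age modes/spreads are synthetic free parameters chosen to sit
#' near published median ages at diagnosis plus a survival lag; they are not
#' estimates of the unpublished age structure.
#'
#' @return List of six [site_profile()] objects.
#' @export
default_paper_profiles <- function() {
  list(
    site_profile("cervix",     4207L, 1.00, 58, 15),
    site_profile("vagina",      411L, 1.00, 70, 13),
    site_profile("vulva",      1262L, 1.00, 72, 13),
    site_profile("penis",       352L, 0.00, 71, 13),
    site_profile("anus",       1169L, 0.63, 64, 13),
    site_profile("oropharynx", 1154L, 0.22, 63, 12))
}

#' Generate a synthetic age/sex-stratified mortality table
#'
#' For each site, ages follow a truncated normal (mean `age_mode`, sd
#' `age_spread`) discretized on 15-100, and sex follows `female_share`; the
#' site's `total_deaths` are allocated multinomially across the (sex, age)
#' cells, so per-site totals are conserved exactly for every seed. With
#' `method = "expected"` the variance-free expected cell counts are returned
#' instead (fractional, same totals).
#'
#' @param profiles List of [site_profile()] objects (one per site).
#' @param seed Integer seed; identical seed and profiles give an identical
#'   table. The caller's RNG state is left untouched.
#' @param method `"multinomial"` (integer draws) or `"expected"`.
#' @return A [mortality_table()] with zero-count cells dropped.
#' @export
generate_mortality <- function(profiles, seed,
                               method = c("multinomial", "expected")) {
  method <- match.arg(method)
  if (inherits(profiles, "site_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "site_profile")))
  if (anyDuplicated(vapply(profiles, `[[`, character(1), "site")))
    stop("duplicate site in profiles", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  ages <- AGE_MIN:AGE_MAX
  pieces <- lapply(profiles, function(p) {
    if (p$total_deaths == 0L)
      return(data.frame(site = character(0), sex = character(0),
                        age = integer(0), deaths = numeric(0)))
    p_age <- stats::dnorm(ages, p$age_mode, p$age_spread)
    p_age <- p_age / sum(p_age)
    sexes <- c("female", "male")
    p_sex <- c(p$female_share, 1 - p$female_share)
    cells <- expand.grid(age = ages, sex = sexes, stringsAsFactors = FALSE)
    p_cell <- rep(p_age, times = 2) * rep(p_sex, each = length(ages))
    counts <- if (method == "multinomial")
      as.numeric(stats::rmultinom(1, p$total_deaths, p_cell))
    else p$total_deaths * p_cell
    keep <- counts > 0
    data.frame(site = p$site, sex = cells$sex[keep], age = cells$age[keep],
               deaths = counts[keep], stringsAsFactors = FALSE)
  })
  mortality_table(do.call(rbind, pieces))
}
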