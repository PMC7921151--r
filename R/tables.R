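#' @keywords internal
"_PACKAGE"

# Anatomy of the analysis: six HPV-associated cancer sites, two sexes,
# single-year ages 15-100. All tabular containers are plain data frames
# carrying an S3 class so that every constructor funnels through a validator.

HPV_SITES <- c("anus", "cervix", "oropharynx", "penis", "vagina", "vulva")
FEMALE_ONLY_SITES <- c("cervix", "vagina", "vulva")
MALE_ONLY_SITES <- "penis"
SEXES <- c("female", "male")
AGE_MIN <- 15L
AGE_MAX <- 100L
HPV_GROUPS <- c("any", "1618", "5types", "9v", "all_deaths")

# Age bins of the economic profile; they exactly partition [15, 100].
ECON_AGE_LO <- c(15L, 16L, 18L, 20L, 25L, 30L, 35L, 40L, 45L, 50L, 55L, 60L, 65L, 70L, 75L)
ECON_AGE_HI <- c(15L, 17L, 19L, 24L, 29L, 34L, 39L, 44L, 49L, 54L, 59L, 64L, 69L, 74L, 100L)

check_sex_site <- function(site, sex) {
  bad_f <- site %in% FEMALE_ONLY_SITES & sex != "female"
  bad_m <- site %in% MALE_ONLY_SITES & sex != "male"
  if (any(bad_f | bad_m)) {
    i <- which(bad_f | bad_m)[1L]
    stop(sprintf("sex-site mismatch: site '%s' cannot have sex '%s'",
                 site[i], sex[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a mortality table
#'
#' Death counts by cancer site, sex and single year of age (15-100). Counts
#' may be fractional: HPV attribution scales integer registry counts by
#' fractions and the product is carried forward unrounded.
#'
#' @param x Data frame with columns `site`, `sex`, `age`, `deaths`.
#' @return A validated `mortality_table` (a data frame).
#' @examples
#' mortality_table(data.frame(site = "cervix", sex = "female", age = 25, deaths = 6))
#' @export
mortality_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  validate_mortality_table(x)
}

#' @rdname mortality_table
#' @export
validate_mortality_table <- function(x) {
  need <- c("site", "sex", "age", "deaths")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("mortality table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- x[, need]
  if (nrow(x) == 0L) {
    x$age <- integer(0); x$deaths <- numeric(0)
    class(x) <- c("mortality_table", "data.frame")
    return(x)
  }
  bad_site <- setdiff(unique(x$site), HPV_SITES)
  if (length(bad_site))
    stop("unknown cancer site(s): ", paste(bad_site, collapse = ", "), call. = FALSE)
  if (!all(x$sex %in% SEXES))
    stop("sex must be one of: ", paste(SEXES, collapse = ", "), call. = FALSE)
  if (any(is.na(x$age)) || any(x$age != as.integer(x$age)))
    stop("ages must be whole numbers", call. = FALSE)
  x$age <- as.integer(x$age)
  out_of_range <- x$age < AGE_MIN | x$age > AGE_MAX
  if (any(out_of_range))
    stop(sprintf("ages outside [%d, %d]: %s", AGE_MIN, AGE_MAX,
                 paste(unique(x$age[out_of_range]), collapse = ", ")), call. = FALSE)
  x$deaths <- as.numeric(x$deaths)
  if (any(!is.finite(x$deaths)) || any(x$deaths < 0))
    stop("death counts must be finite and non-negative", call. = FALSE)
  check_sex_site(x$site, x$sex)
  key <- paste(x$site, x$sex, x$age)
  if (anyDuplicated(key))
    stop("duplicate (site, sex, age) entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  x <- x[order(x$site, x$sex, x$age), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("mortality_table", "data.frame")
  x
}

#' Construct an HPV attribution table
#'
#' Per (site, sex) fractions of cancers attributable to any HPV
#' (`f_any`), to HPV 16/18 (`f_1618`), and to HPV 31/33/45/52/58
#' (`f_5types`). Fractions are stored on the 0-1 scale; the on-disk format
#' uses percentages (see [read_attribution()]). Every row must satisfy
#' `f_1618 + f_5types <= f_any <= 1`.
#'
#' @param x Data frame with columns `site`, `sex`, `f_any`, `f_1618`, `f_5types`.
#' @return A validated `attribution_table`.
#' @export
attribution_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("site", "sex", "f_any", "f_1618", "f_5types")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("attribution table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- x[, need]
  bad_site <- setdiff(unique(x$site), HPV_SITES)
  if (length(bad_site))
    stop("unknown cancer site(s): ", paste(bad_site, collapse = ", "), call. = FALSE)
  if (!all(x$sex %in% SEXES))
    stop("attribution sex must be 'female' or 'male'", call. = FALSE)
  check_sex_site(x$site, x$sex)
  for (col in c("f_any", "f_1618", "f_5types")) {
    v <- as.numeric(x[[col]])
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop(col, " must lie in [0, 1] (percent inputs belong in read_attribution)",
           call. = FALSE)
    x[[col]] <- v
  }
  viol <- x$f_1618 + x$f_5types > x$f_any + 1e-9
  if (any(viol))
    stop("attribution ordering violated (f_1618 + f_5types > f_any) for: ",
         paste(paste(x$site[viol], x$sex[viol]), collapse = "; "), call. = FALSE)
  if (anyDuplicated(paste(x$site, x$sex)))
    stop("duplicate attribution rows for a (site, sex)", call. = FALSE)
  rownames(x) <- NULL
  class(x) <- c("attribution_table", "data.frame")
  x
}

#' Construct a life table
#'
#' Remaining life expectancy by sex and single year of age. Coverage of ages
#' 15-100 must be complete for each sex present; expectancy must be strictly
#' positive below age 100 and can never exceed `115 - age`.
#'
#' @param x Data frame with columns `sex`, `age`, `ex` (years).
#' @return A validated `life_table`.
#' @export
life_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("sex", "age", "ex")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("life table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- x[, need]
  if (!all(x$sex %in% SEXES))
    stop("life-table sex must be 'female' or 'male'", call. = FALSE)
  x$age <- as.integer(x$age)
  x$ex <- as.numeric(x$ex)
  if (any(!is.finite(x$ex)) || any(x$ex < 0))
    stop("life expectancy must be finite and non-negative", call. = FALSE)
  if (any(x$ex == 0 & x$age < AGE_MAX))
    stop("life expectancy must be strictly positive below age 100", call. = FALSE)
  if (any(x$ex > 115 - x$age))
    stop("life expectancy exceeds the 115 - age sanity bound", call. = FALSE)
  for (s in unique(x$sex)) {
    have <- x$age[x$sex == s]
    gaps <- setdiff(AGE_MIN:AGE_MAX, have)
    if (length(gaps))
      stop(sprintf("life table for sex '%s' is missing age(s): %s", s,
                   paste(gaps, collapse = ", ")), call. = FALSE)
    if (anyDuplicated(have))
      stop(sprintf("life table for sex '%s' has duplicate ages", s), call. = FALSE)
  }
  x <- x[order(x$sex, x$age), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("life_table", "data.frame")
  x
}

#' Construct an economic profile
#'
#' Age-bin by sex economic inputs for the human-capital productivity model:
#' labor-force participation (probability), median weekly wage (USD), and the
#' annual value of non-market household/caregiving work (USD/year), together
#' with the global fringe-benefit markup, discount rate and reference year.
#' The age bins must exactly partition ages 15-100 into the fifteen bins
#' `{15}`, `[16,17]`, `[18,19]`, `[20,24]`, five-year bins to `[70,74]`, and
#' `[75,100]`; the age-15 bin carries zero productivity by convention.
#'
#' @param bins Data frame with columns `age_lo`, `age_hi`, `sex`,
#'   `participation` (0-1), `weekly_wage`, `nonmarket_annual`.
#' @param markup Fringe-benefit markup converting wages to total compensation.
#' @param discount_rate Annual discount rate used to bring future values to
#'   the reference year.
#' @param reference_year Calendar year of the analysis (dollars and deaths).
#' @return An `econ_profile` object (list of bins plus scalars).
#' @export
econ_profile <- function(bins, markup = 1.464, discount_rate = 0.03,
                         reference_year = 2017L) {
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  need <- c("age_lo", "age_hi", "sex", "participation", "weekly_wage",
            "nonmarket_annual")
  miss <- setdiff(need, names(bins))
  if (length(miss))
    stop("economic profile is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bins <- bins[, need]
  if (!all(bins$sex %in% SEXES))
    stop("economic-profile sex must be 'female' or 'male'", call. = FALSE)
  for (s in SEXES) {
    b <- bins[bins$sex == s, ]
    b <- b[order(b$age_lo), ]
    if (!identical(as.integer(b$age_lo), ECON_AGE_LO) ||
        !identical(as.integer(b$age_hi), ECON_AGE_HI))
      stop(sprintf("economic-profile bins for sex '%s' must partition [15, 100] into the standard 15 bins", s),
           call. = FALSE)
  }
  for (col in c("participation", "weekly_wage", "nonmarket_annual"))
    bins[[col]] <- as.numeric(bins[[col]])
  if (any(bins$participation < 0 | bins$participation > 1))
    stop("participation must lie in [0, 1]", call. = FALSE)
  if (any(bins$weekly_wage < 0) || any(bins$nonmarket_annual < 0))
    stop("monetary values must be non-negative", call. = FALSE)
  if (!is.finite(markup) || markup <= 0) stop("markup must be positive", call. = FALSE)
  if (!is.finite(discount_rate) || discount_rate < 0)
    stop("discount_rate must be non-negative", call. = FALSE)
  bins <- bins[order(bins$sex, bins$age_lo), ]
  rownames(bins) <- NULL
  structure(
    list(bins = bins, markup = markup, discount_rate = discount_rate,
         reference_year = as.integer(reference_year)),
    class = "econ_profile")
}

#' @export
print.econ_profile <- function(x, ...) {
  cat(sprintf("Economic profile (%d US$, markup %.3f, discount %.1f%%)\n",
              x$reference_year, x$markup, 100 * x$discount_rate))
  print(x$bins, ...)
  invisible(x)
}

#' @export
print.mortality_table <- function(x, ...) {
  cat(sprintf("Mortality table: %d entries, %.7g deaths across %d site-sex strata\n",
              nrow(x), sum(x$deaths), length(unique(paste(x$site, x$sex)))))
  NextMethod()
}

# fast lookup of remaining life expectancy; vectorized over age/sex
life_expectancy <- function(lt, sex, age) {
  i <- match(paste(sex, age), paste(lt$sex, lt$age))
  if (anyNA(i))
    stop("age(s) outside life-table coverage: ",
         paste(unique(paste(sex, age)[is.na(i)]), collapse = ", "), call. = FALSE)
  lt$ex[i]
}
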