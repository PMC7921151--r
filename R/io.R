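# Readers and writers. Percentages live on the 0-100 scale on disk and the
# 0-1 scale in memory; the conversion happens here and nowhere else.

#' Path to a packaged input table
#'
#' @param file One of `"attribution_us_2008_2010.csv"`,
#'   `"econ_profile_us_2017.csv"`, `"life_table_2016_synthetic.csv"`; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
hpvburden_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "hpvburden")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file: ", file, call. = FALSE)
  path
}

#' Read an age/sex-stratified mortality table
#'
#' Two dialects are supported. `csv`: a plain table with header
#' `site,sex,age,deaths`. `wonder`: a CDC WONDER-style tab-delimited export
#' with `Single-Year Ages Code`, `Gender` and `Deaths` columns and an ICD-10
#' code column which is mapped to a cancer site via `code_map`; the trailing
#' provenance block (a line of dashes or the "Notes" text) is discarded, and
#' the `100+` terminal age bucket is mapped to age 100. Suppressed counts are
#' an error: the affected rows are listed so the user can re-extract with
#' coarser strata rather than silently under-count.
#'
#' @param path File to read.
#' @param dialect `"csv"` or `"wonder"`.
#' @param code_map Named character vector mapping ICD-10 codes to sites
#'   (wonder dialect only). The default maps C53, C51, C52, C60, C21 and all
#'   of C00-C14; pass a restricted map to use an oropharyngeal code subset.
#' @param code_col Name of the ICD-10 code column (wonder dialect); guessed
#'   from common WONDER export headers when `NULL`.
#' @return A [mortality_table()].
#' @export
read_mortality <- function(path, dialect = c("csv", "wonder"),
                           code_map = wonder_code_map(), code_col = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("site", "sex", "age", "deaths")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("malformed header: missing column(s) ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (nrow(x) == 0L) stop("no records in ", path, call. = FALSE)
    return(mortality_table(x))
  }
  read_mortality_wonder(path, code_map = code_map, code_col = code_col)
}

#' Default ICD-10 code to cancer-site map for WONDER exports
#'
#' C53 cervix, C51 vulva, C52 vagina, C60 penis, C21 anus, and the full
#' C00-C14 range for the oropharyngeal group (both the range label and the
#' individual codes are accepted).
#'
#' @return Named character vector (names are ICD-10 codes, values are sites).
#' @export
wonder_code_map <- function() {
  oro <- sprintf("C%02d", 0:14)
  c(C53 = "cervix", C51 = "vulva", C52 = "vagina", C60 = "penis",
    C21 = "anus", `C00-C14` = "oropharynx",
    stats::setNames(rep("oropharynx", length(oro)), oro))
}

read_mortality_wonder <- function(path, code_map = wonder_code_map(),
                                  code_col = NULL) {
  lines <- readLines(path, warn = FALSE)
  cut <- which(!nzchar(trimws(lines)) | startsWith(trimws(lines), "---"))
  if (length(cut)) lines <- lines[seq_len(min(cut) - 1L)]
  if (length(lines) < 2L) stop("no records in ", path, call. = FALSE)
  x <- utils::read.delim(text = paste(lines, collapse = "\n"),
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if ("Notes" %in% names(x)) x <- x[!nzchar(trimws(x$Notes)), , drop = FALSE]
  if (nrow(x) == 0L) stop("no records in ", path, call. = FALSE)
  if (is.null(code_col)) {
    candidates <- c("ICD Sub-Chapter Code", "ICD-10 Code",
                    "Cause of death Code", "ICD Chapter Code")
    code_col <- intersect(candidates, names(x))[1]
    if (is.na(code_col))
      stop("malformed header: no ICD-10 code column found (looked for: ",
           paste(candidates, collapse = ", "), ")", call. = FALSE)
  }
  need <- c("Single-Year Ages Code", "Gender", "Deaths", code_col)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  supp <- grepl("suppressed", x$Deaths, ignore.case = TRUE)
  if (any(supp)) {
    rows <- x[supp, need]
    stop("suppressed death counts cannot be used; offending rows: ",
         paste(sprintf("[%s %s age %s]", rows[[code_col]], rows$Gender,
                       rows[["Single-Year Ages Code"]]), collapse = " "),
         call. = FALSE)
  }
  codes <- trimws(x[[code_col]])
  site <- unname(code_map[codes])
  if (anyNA(site))
    stop("unknown site code(s): ",
         paste(unique(codes[is.na(site)]), collapse = ", "), call. = FALSE)
  age_code <- trimws(x[["Single-Year Ages Code"]])
  age <- ifelse(age_code %in% c("100+", "100"), 100L,
                suppressWarnings(as.integer(age_code)))
  if (anyNA(age))
    stop("unparseable age code(s): ",
         paste(unique(age_code[is.na(age)]), collapse = ", "), call. = FALSE)
  out <- data.frame(site = site, sex = tolower(trimws(x$Gender)), age = age,
                    deaths = as.numeric(x$Deaths), stringsAsFactors = FALSE)
  # the same site can arrive under several codes (C00..C14): pool them
  out <- stats::aggregate(deaths ~ site + sex + age, data = out, FUN = sum)
  mortality_table(out)
}

#' Read an HPV attribution table
#'
#' Expects header `site,sex,pct_any_hpv,pct_hpv_16_18,pct_hpv_31_33_45_52_58`
#' with percentages on the 0-100 scale; `sex` may be blank for the single-sex
#' sites (cervix, vagina, vulva, penis) and is then filled in. Fractions are
#' stored on the 0-1 scale and the ordering invariant
#' `f_1618 + f_5types <= f_any` is enforced.
#'
#' @param path File to read.
#' @return An [attribution_table()].
#' @export
read_attribution <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                       colClasses = c(sex = "character"))
  need <- c("site", "sex", "pct_any_hpv", "pct_hpv_16_18",
            "pct_hpv_31_33_45_52_58")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  sex <- trimws(x$sex)
  blank <- !nzchar(sex) | is.na(sex)
  sex[blank & x$site %in% FEMALE_ONLY_SITES] <- "female"
  sex[blank & x$site %in% MALE_ONLY_SITES] <- "male"
  if (any(!nzchar(sex)))
    stop("sex must be given for two-sex sites (anus, oropharynx)", call. = FALSE)
  pct <- c("pct_any_hpv", "pct_hpv_16_18", "pct_hpv_31_33_45_52_58")
  if (any(x[pct] < 0) || any(x[pct] > 100))
    stop("attribution percentages must lie in [0, 100]", call. = FALSE)
  attribution_table(data.frame(
    site = x$site, sex = sex,
    f_any = x$pct_any_hpv / 100,
    f_1618 = x$pct_hpv_16_18 / 100,
    f_5types = x$pct_hpv_31_33_45_52_58 / 100,
    stringsAsFactors = FALSE))
}

#' Read a life table
#'
#' Expects header `sex,age,life_expectancy_years` and complete single-year
#' coverage of ages 15-100 for each sex present.
#'
#' @param path File to read.
#' @return A [life_table()].
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sex", "age", "life_expectancy_years")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  life_table(data.frame(sex = x$sex, age = x$age,
                        ex = x$life_expectancy_years,
                        stringsAsFactors = FALSE))
}

#' Read an economic profile
#'
#' Expects header
#' `age_lo,age_hi,sex,participation_pct,weekly_wage_usd,nonmarket_annual_usd`
#' with participation on the 0-100 scale. Markup, discount rate and reference
#' year are scalars supplied here (they are configuration, not table rows).
#'
#' @param path File to read.
#' @inheritParams econ_profile
#' @return An [econ_profile()].
#' @export
read_econ_profile <- function(path, markup = 1.464, discount_rate = 0.03,
                              reference_year = 2017L) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("age_lo", "age_hi", "sex", "participation_pct", "weekly_wage_usd",
            "nonmarket_annual_usd")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("malformed header: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  econ_profile(
    data.frame(age_lo = x$age_lo, age_hi = x$age_hi, sex = x$sex,
               participation = x$participation_pct / 100,
               weekly_wage = x$weekly_wage_usd,
               nonmarket_annual = x$nonmarket_annual_usd,
               stringsAsFactors = FALSE),
    markup = markup, discount_rate = discount_rate,
    reference_year = reference_year)
}

#' Write a mortality table as CSV
#'
#' Deterministic row order (site, sex, age) so that identical tables
#' serialize byte-identically.
#'
#' @param x A [mortality_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mortality <- function(x, path) {
  x <- validate_mortality_table(x)
  df <- data.frame(site = x$site, sex = x$sex, age = x$age,
                   deaths = num_full(x$deaths), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal rendering that survives a read.csv round trip
num_full <- function(x) {
  out <- vapply(x, function(v) {
    if (!is.finite(v)) return(as.character(v))
    sprintf("%.17g", v)
  }, character(1))
  out
}

round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Write burden results as report tables
#'
#' Produces two CSV files mirroring the standard burden-report layout:
#' `deaths_ypll.csv` (attributable deaths, YPLL and YPLL per death) and
#' `pvflp.csv` (market, non-market and total PVFLP, the total rounded to
#' thousands, percent of each group's total, and PVFLP per death). Monetary
#' values are written at full precision alongside the rounded columns, so a
#' read-back reproduces every stored number exactly. Rows are ordered with
#' females first, sites alphabetical within sex, and any whole-population
#' total row last within its group.
#'
#' @param result A `burden_result` data frame from [total_burden()] or
#'   [compute_burden()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  res <- as.data.frame(result, stringsAsFactors = FALSE)
  ord <- order(match(res$hpv_group, unique(res$hpv_group)),
               res$site == "total",
               match(res$sex, c("female", "male", "all")),
               res$site)
  res <- res[ord, , drop = FALSE]

  dy <- data.frame(hpv_group = res$hpv_group, sex = res$sex, site = res$site,
                   deaths = num_full(res$deaths),
                   deaths_rounded = round_half_up(res$deaths),
                   ypll = num_full(res$ypll),
                   ypll_per_death = num_full(res$ypll_per_death),
                   stringsAsFactors = FALSE)
  f1 <- file.path(dir, "deaths_ypll.csv")
  utils::write.csv(dy, f1, row.names = FALSE, quote = FALSE)

  pct <- rep(NA_real_, nrow(res))
  for (g in unique(res$hpv_group)) {
    in_g <- res$hpv_group == g
    strata <- in_g & res$site != "total"
    denom <- if (any(in_g & res$site == "total"))
      res$pvflp_total[in_g & res$site == "total"][1]
    else sum(res$pvflp_total[strata])
    if (denom > 0) pct[in_g] <- 100 * res$pvflp_total[in_g] / denom
  }
  pv <- data.frame(hpv_group = res$hpv_group, sex = res$sex, site = res$site,
                   pvflp_market = num_full(res$pvflp_market),
                   pvflp_nonmarket = num_full(res$pvflp_nonmarket),
                   pvflp_total = num_full(res$pvflp_total),
                   pvflp_total_thousands = round_half_up(res$pvflp_total / 1000),
                   pct_of_total_pvflp = round_half_up(pct, 1),
                   pvflp_per_death = num_full(res$pvflp_per_death),
                   stringsAsFactors = FALSE)
  f2 <- file.path(dir, "pvflp.csv")
  utils::write.csv(pv, f2, row.names = FALSE, quote = FALSE)
  invisible(c(deaths_ypll = f1, pvflp = f2))
}

#' Read back report tables written by [write_results()]
#'
#' @param dir Directory holding `deaths_ypll.csv` and `pvflp.csv`.
#' @return List with elements `deaths_ypll` and `pvflp` (data frames with
#'   numeric columns restored).
#' @export
read_results <- function(dir) {
  dy <- utils::read.csv(file.path(dir, "deaths_ypll.csv"),
                        stringsAsFactors = FALSE)
  pv <- utils::read.csv(file.path(dir, "pvflp.csv"), stringsAsFactors = FALSE)
  list(deaths_ypll = dy, pvflp = pv)
}
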