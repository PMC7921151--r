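# Fixtures built in code. Packaged input tables are loaded through the
# installed package; tiny synthetic tables are constructed here.

load_fixture_attribution <- function() {
  read_attribution(hpvburden_extdata("attribution_us_2008_2010.csv"))
}

load_fixture_life_table <- function() {
  read_life_table(hpvburden_extdata("life_table_2016_synthetic.csv"))
}

load_fixture_econ <- function(...) {
  read_econ_profile(hpvburden_extdata("econ_profile_us_2017.csv"), ...)
}

# a simple strictly decreasing life table with known closed form
linear_life_table <- function(slope = 0.8, top = 105) {
  grid <- expand.grid(age = 15:100, sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  grid$ex <- slope * (top - grid$age)
  life_table(grid)
}

# a constant-expectancy life table (legal: e <= 115 - age holds for e <= 15)
constant_life_table <- function(e) {
  grid <- expand.grid(age = 15:100, sex = c("female", "male"),
                      stringsAsFactors = FALSE)
  grid$ex <- e
  life_table(grid)
}

random_mortality <- function(n = 50, seed = 42) {
  set.seed(seed)
  sites <- sample(c("cervix", "vagina", "vulva", "anus", "oropharynx",
                    "penis"), n, replace = TRUE)
  sex <- ifelse(sites %in% c("cervix", "vagina", "vulva"), "female",
         ifelse(sites == "penis", "male",
                sample(c("female", "male"), n, replace = TRUE)))
  df <- data.frame(site = sites, sex = sex,
                   age = sample(15:100, n, replace = TRUE),
                   deaths = round(runif(n, 0, 40), 2),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("site", "sex", "age")]), ]
  mortality_table(df)
}

# a small WONDER-style export written to a temp file
write_wonder_fixture <- function(rows, trailer = TRUE) {
  header <- paste("Notes", "Single-Year Ages", "Single-Year Ages Code",
                  "Gender", "ICD Sub-Chapter Code", "Deaths", sep = "\t")
  body <- vapply(rows, function(r)
    paste("", r$age_label, r$age_code, r$gender, r$code, r$deaths,
          sep = "\t"), character(1))
  lines <- c(header, body)
  if (trailer)
    lines <- c(lines, "---", "Dataset: Underlying Cause of Death, 1999-2017",
               "Query date: synthetic")
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

wonder_row <- function(code, gender, age_code, deaths,
                       age_label = paste(age_code, "years")) {
  list(code = code, gender = gender, age_code = age_code, deaths = deaths,
       age_label = age_label)
}
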