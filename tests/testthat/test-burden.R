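test_that("YPLL per death is the remaining life expectancy, exactly", {
  lt <- load_fixture_life_table()
  expect_identical(ypll_for_death(25, "female", lt), 57)
  expect_identical(ypll_for_death(c(25, 25), c("female", "male"), lt)[2],
                   lt$ex[lt$sex == "male" & lt$age == 25])
  expect_error(ypll_for_death(14, "female", lt), "outside")
  expect_error(ypll_for_death(101, "female", lt), "outside")
})

test_that("stratum YPLL sums count x expectancy and is additive", {
  lt <- load_fixture_life_table()
  one <- mortality_table(data.frame(site = "cervix", sex = "female",
                                    age = 25, deaths = 5.46))
  expect_equal(total_ypll(one, lt)$ypll, 311.22)

  d <- random_mortality(n = 50, seed = 13)
  got <- total_ypll(d, lt)
  # brute-force per-entry loop oracle
  want <- numeric(nrow(got))
  for (i in seq_len(nrow(got))) {
    rows <- d[d$site == got$site[i] & d$sex == got$sex[i], ]
    s <- 0
    for (j in seq_len(nrow(rows)))
      s <- s + rows$deaths[j] *
        lt$ex[lt$sex == rows$sex[j] & lt$age == rows$age[j]]
    want[i] <- s
  }
  expect_equal(got$ypll, want, tolerance = 1e-9)
  # additivity over strata
  half1 <- d[seq(1, nrow(d), 2), ]; half2 <- d[seq(2, nrow(d), 2), ]
  expect_equal(sum(total_ypll(d, lt)$ypll),
               sum(total_ypll(mortality_table(half1), lt)$ypll) +
               sum(total_ypll(mortality_table(half2), lt)$ypll))
})

test_that("annual market value reproduces the per-week and annualized scales", {
  econ <- load_fixture_econ()
  printed <- pvflp_settings(annualization = "as_printed")
  weekly <- pvflp_settings(annualization = "weeks52")
  expect_equal(annual_market_value(27, "female", econ, printed), 809.79,
               tolerance = 0.005 / 809.79)
  expect_equal(annual_market_value(32, "female", econ, printed), 789.65,
               tolerance = 0.005 / 789.65)
  expect_identical(annual_market_value(15, "female", econ, printed), 0)
  expect_identical(annual_market_value(15, "male", econ, weekly), 0)
  expect_equal(annual_market_value(27, "female", econ, weekly),
               52 * annual_market_value(27, "female", econ, printed))
})

test_that("annual non-market value is a plain bin lookup", {
  econ <- load_fixture_econ()
  expect_identical(annual_nonmarket_value(27, "female", econ), 33087)
  expect_identical(annual_nonmarket_value(15, "male", econ), 0)
  expect_identical(annual_nonmarket_value(80, "male", econ), 11896)
  # attained ages beyond 100 fall back to the terminal 75+ bin
  expect_identical(annual_nonmarket_value(104, "female", econ),
                   annual_nonmarket_value(80, "female", econ))
  expect_identical(annual_market_value(104, "male", econ),
                   annual_market_value(80, "male", econ))
})

test_that("single-year discounting identities hold", {
  econ <- load_fixture_econ()
  lt1 <- constant_life_table(1)  # exactly one lost year at age + 1
  v_at <- function(k, s) annual_market_value(k, "female", econ, s) +
    annual_nonmarket_value(k, "female", econ)

  s0 <- pvflp_settings(discount_rate = 0)
  pv0 <- pvflp_for_death(40, "female", lt1, econ, s0)
  expect_equal(unname(sum(pv0)), v_at(41, s0))

  s3 <- pvflp_settings(discount_rate = 0.03)
  pv3 <- pvflp_for_death(40, "female", lt1, econ, s3)
  expect_equal(unname(sum(pv3)), v_at(41, s3) / 1.03)
})

test_that("fractional final-year handling adds a weighted extra year", {
  econ <- load_fixture_econ()
  lt <- constant_life_table(1.5)
  s_tr <- pvflp_settings(discount_rate = 0.03, final_year_handling = "truncate")
  s_fr <- pvflp_settings(discount_rate = 0.03,
                         final_year_handling = "fractional")
  tr <- pvflp_for_death(40, "male", lt, econ, s_tr)
  fr <- pvflp_for_death(40, "male", lt, econ, s_fr)
  extra_m <- 0.5 * annual_market_value(42, "male", econ, s_fr) / 1.03^2
  extra_n <- 0.5 * annual_nonmarket_value(42, "male", econ) / 1.03^2
  expect_equal(unname(fr["market"] - tr["market"]), extra_m)
  expect_equal(unname(fr["nonmarket"] - tr["nonmarket"]), extra_n)
})

test_that("discounted stream matches the independent per-year oracle", {
  econ <- load_fixture_econ()
  lt <- load_fixture_life_table()
  set.seed(99)
  for (i in 1:100) {
    age <- sample(15:100, 1)
    sex <- sample(c("female", "male"), 1)
    r <- runif(1, 0, 0.1)
    final <- sample(c("truncate", "fractional"), 1)
    s <- pvflp_settings(discount_rate = r, final_year_handling = final)
    got <- pvflp_for_death(age, sex, lt, econ, s)
    want <- oracle_pvflp(age, sex, lt, econ$bins, r, s$markup, weeks = 52,
                         final = final)
    expect_equal(got, want, tolerance = 1e-9)
  }
  # discounting strictly shrinks a non-degenerate stream
  s0 <- pvflp_settings(discount_rate = 0)
  s3 <- pvflp_settings(discount_rate = 0.03)
  expect_gt(sum(pvflp_for_death(25, "female", lt, econ, s0)),
            sum(pvflp_for_death(25, "female", lt, econ, s3)))
})

test_that("whole-table burden conserves, scales linearly, and commutes with attribution", {
  econ <- load_fixture_econ()
  lt <- load_fixture_life_table()
  d <- generate_mortality(default_paper_profiles(), seed = 21)
  res <- total_burden(d, lt, econ)
  strata <- res[res$site != "total", ]
  tot <- res[res$site == "total", ]
  for (col in c("deaths", "ypll", "pvflp_market", "pvflp_nonmarket",
                "pvflp_total"))
    expect_equal(sum(strata[[col]]), tot[[col]], tolerance = 1e-9)
  expect_equal(res$pvflp_total, res$pvflp_market + res$pvflp_nonmarket)
  expect_equal(res$ypll_per_death, res$ypll / res$deaths)

  d2 <- d; d2$deaths <- 2 * d2$deaths
  res2 <- total_burden(d2, lt, econ)
  expect_equal(res2$deaths, 2 * res$deaths)
  expect_equal(res2$ypll, 2 * res$ypll)
  expect_equal(res2$pvflp_total, 2 * res$pvflp_total)
  expect_equal(res2$pvflp_per_death, res$pvflp_per_death)

  f <- 0.37
  datt <- d; datt$deaths <- f * datt$deaths
  resf <- total_burden(datt, lt, econ)
  expect_equal(resf$ypll, f * res$ypll, tolerance = 1e-12)
  expect_equal(resf$pvflp_total, f * res$pvflp_total, tolerance = 1e-12)
})

test_that("degenerate burden inputs give zero or single-stratum results", {
  econ <- load_fixture_econ()
  lt <- load_fixture_life_table()
  empty <- mortality_table(data.frame(site = character(0),
                                      sex = character(0), age = integer(0),
                                      deaths = numeric(0)))
  res0 <- total_burden(empty, lt, econ)
  expect_identical(res0$deaths, 0)
  expect_identical(res0$pvflp_total, 0)
  expect_true(is.na(res0$ypll_per_death))

  one <- mortality_table(data.frame(site = "penis", sex = "male", age = 70,
                                    deaths = 10))
  res1 <- total_burden(one, lt, econ)
  expect_identical(nrow(res1), 2L)
  expect_equal(res1$pvflp_total[1], res1$pvflp_total[2])
})
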