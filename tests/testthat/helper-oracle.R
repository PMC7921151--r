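# Independent per-year accumulation oracle for the discounted productivity
# stream. Deliberately written as a naive scan-the-bins loop, separate from
# the package's vectorized bin lookup.

oracle_bin <- function(bins, sex, k) {
  kk <- min(k, 100)
  for (i in seq_len(nrow(bins))) {
    if (bins$sex[i] == sex && kk >= bins$age_lo[i] && kk <= bins$age_hi[i])
      return(bins[i, ])
  }
  stop("no economic bin for age ", k)
}

oracle_pvflp <- function(age, sex, lt, bins, r, markup, weeks = 52,
                         offset = 1, final = "truncate") {
  L <- lt$ex[lt$sex == sex & lt$age == age]
  n <- floor(L)
  fr <- L - n
  ks <- if (age + n >= age + offset) (age + offset):(age + n) else integer(0)
  ws <- rep(1, length(ks))
  if (final == "fractional" && fr > 0) {
    ks <- c(ks, age + n + 1)
    ws <- c(ws, fr)
  }
  market <- 0
  nonmarket <- 0
  for (j in seq_along(ks)) {
    b <- oracle_bin(bins, sex, ks[j])
    d <- 1 / (1 + r)^(ks[j] - age)
    market <- market + ws[j] * d * b$participation * b$weekly_wage * weeks * markup
    nonmarket <- nonmarket + ws[j] * d * b$nonmarket_annual
  }
  c(market = market, nonmarket = nonmarket)
}
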