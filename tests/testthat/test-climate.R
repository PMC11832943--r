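make_table <- function(value_fun, years = 1990:2021, variable = "temperature",
                       station = "S1") {
  df <- expand.grid(month = 1:12, year = years)
  df$value <- value_fun(df$year, df$month)
  climate_table(station, variable, df)
}

test_that("station standardization gives per-month z-scores", {
  set.seed(61)
  tab <- make_table(function(y, m) 10 + 2 * (y %% 7 - 3) / 2, 1992:2021)
  dep <- standardize_station(tab, c(1992, 2021))
  # reference-period departures have mean 0 and sd 1, month by month
  for (m in c(1, 6, 12)) {
    z <- dep$value[dep$month == m & dep$year >= 1992 & dep$year <= 2021]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  # a month outside the reference period standardizes against the
  # reference climatology of that month
  df <- expand.grid(month = 1:12, year = 1992:2022)
  set.seed(62)
  per_year <- rnorm(31, 0, 1)
  df$value <- 10 + 2 * per_year[df$year - 1991]
  tab2 <- climate_table("S2", "temperature", df)
  dep2 <- standardize_station(tab2, c(1992, 2021))
  mu <- mean(10 + 2 * per_year[1:30]); s <- sd(10 + 2 * per_year[1:30])
  expect_equal(dep2$value[dep2$year == 2022 & dep2$month == 1],
               (10 + 2 * per_year[31] - mu) / s, tolerance = 1e-10)
})

test_that("standardization is affine-invariant and guards degenerate input", {
  set.seed(63)
  df <- expand.grid(month = 1:12, year = 1990:2021)
  df$value <- rnorm(nrow(df), 5, 3)
  tab_c <- climate_table("SC", "temperature", df)
  df_f <- df
  df_f$value <- df$value * 9 / 5 + 32   # Celsius -> Fahrenheit
  tab_f <- climate_table("SF", "temperature", df_f)
  expect_equal(standardize_station(tab_c, c(1992, 2021))$value,
               standardize_station(tab_f, c(1992, 2021))$value,
               tolerance = 1e-10)
  df0 <- df; df0$value <- 4
  expect_error(standardize_station(climate_table("S0", "temperature", df0),
                                   c(1992, 2021)), "zero")
  expect_error(standardize_station(tab_c, c(2010, 2021)), "reference years")
})

test_that("regional means average available stations with equal weight", {
  mk_dep <- function(v, yrs = 2000:2001) {
    climate_departure("temperature",
                      within(expand.grid(month = 1:12, year = yrs),
                             value <- v),
                      c(1992, 2021))
  }
  plus <- mk_dep(1); minus <- mk_dep(-1)
  rm0 <- regional_mean(list(plus, minus))
  expect_equal(rm0$value, rep(0, 24))
  expect_equal(rm0$n_stations, rep(2L, 24))
  expect_equal(regional_mean(list(plus))$value, plus$value)
  # a station missing one month: mean over the remaining ones
  short <- mk_dep(0.5)
  short <- short[!(short$year == 2000 & short$month == 3), ]
  class(short) <- c("climate_departure", "data.frame")
  attr(short, "variable") <- "temperature"; attr(short, "reference") <- c(1992L, 2021L)
  rm2 <- regional_mean(list(plus, minus, short))
  cell <- rm2[rm2$year == 2000 & rm2$month == 3, ]
  expect_equal(cell$value, 0)
  expect_equal(cell$n_stations, 2L)
  other <- rm2[rm2$year == 2000 & rm2$month == 4, ]
  expect_equal(other$value, 0.5 / 3)
  expect_equal(other$n_stations, 3L)
})

test_that("the moisture index is precipitation minus temperature departure", {
  grid <- expand.grid(month = 1:12, year = 2000)
  mk <- function(v, var) climate_departure(var, within(grid, value <- v),
                                           c(1992, 2021))
  expect_equal(moisture_index(mk(1, "precipitation"),
                              mk(-1, "temperature"))$value, rep(2, 12))
  expect_equal(moisture_index(mk(0, "precipitation"),
                              mk(0, "temperature"))$value, rep(0, 12))
  expect_equal(moisture_index(mk(-1, "precipitation"),
                              mk(1, "temperature"))$value, rep(-2, 12))
  # antisymmetric under swapping the two roles
  set.seed(64)
  p <- mk(rnorm(12), "precipitation"); t <- mk(rnorm(12), "temperature")
  t2 <- t; attr(t2, "variable") <- "precipitation"
  p2 <- p; attr(p2, "variable") <- "temperature"
  expect_equal(moisture_index(p, t)$value, -moisture_index(t2, p2)$value)
  # misaligned coverage: intersection with a warning
  t3 <- t[t$month <= 6, ]
  class(t3) <- class(t); attr(t3, "variable") <- "temperature"
  attr(t3, "reference") <- c(1992L, 2021L)
  expect_warning(mi <- moisture_index(p, t3), "intersection")
  expect_equal(nrow(mi), 6L)
})

test_that("the 19-month season window enumerates exactly as defined", {
  w <- season_window(2000)
  expect_equal(nrow(w), 19L)
  expect_equal(w$year, c(rep(1998L, 3), rep(1999L, 12), rep(2000L, 4)))
  expect_equal(w$month, c(10:12, 1:12, 1:4))
  expect_equal(w$label[1], "prev.Oct")
  expect_equal(w$label[19], "curr.Apr")
  expect_equal(w$label[8:12], paste0("win.", month.abb[5:9]))
  expect_equal(w$label[13], "curr.Oct")
  # unique (year, month) pairs
  expect_false(anyDuplicated(w[, c("year", "month")]) > 0)
  # consecutive growth years overlap by 7 months
  w2 <- season_window(2001)
  expect_equal(nrow(merge(w, w2, by = c("year", "month"))), 7L)
})
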