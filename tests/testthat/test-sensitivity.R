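# departure table where one chosen month carries a prescribed annual
# signal and the others carry independent noise
signal_departure <- function(signal_by_year, years, month_signal = 2,
                             variable = "temperature", seed = 1) {
  set.seed(seed)
  df <- expand.grid(month = 1:12, year = years)
  df$value <- rnorm(nrow(df))
  hit <- df$month == month_signal
  df$value[hit] <- signal_by_year[match(df$year[hit], years)]
  climate_departure(variable, df, range(years))
}

test_that("a chronology equal to a monthly departure correlates at 1 there", {
  years <- 1930:2021
  sig <- as.numeric(scale(rnorm(length(years))))
  dep <- signal_departure(sig, years, month_signal = 2, seed = 71)
  chron <- index_series("site", 1930L, sig)
  res <- monthly_correlations(chron, dep, c(1931, 2021), n_boot = 300,
                              seed = 72)
  expect_length(res$r, 19L)
  expect_length(res$significant, 19L)
  feb <- which(res$labels == "curr.Feb")
  expect_equal(res$r[feb], 1, tolerance = 1e-9)
  expect_true(res$significant[feb])
  expect_error(monthly_correlations(chron, dep, c(2010, 2021),
                                    n_boot = 100, seed = 1), "< 30")
  expect_error(monthly_correlations(chron, dep, c(1931, 2021), 100),
               "seed")
})

test_that("bootstrap significance has ~5% false positives on white noise", {
  years <- 1929:2021
  counts <- c()
  for (seed in 1:12) {
    set.seed(seed)
    dep <- signal_departure(rnorm(length(years)), years, month_signal = 0,
                            seed = seed + 500)
    chron <- index_series("noise", 1931L, rnorm(91))
    res <- monthly_correlations(chron, dep, c(1931, 2021), n_boot = 400,
                                seed = seed)
    counts <- c(counts, sum(res$significant))
  }
  # 19 slots at a 5% level: about one false positive per run
  expect_lte(mean(counts), 2)
})

test_that("seasonal sensitivity averages slot correlations", {
  years <- 1930:2021
  sig <- as.numeric(scale(rnorm(length(years))))
  # identical signal in Dec (offset year) is impossible in one table; use
  # Jan/Feb/Mar of the growth year (the JFM aggregate)
  set.seed(73)
  df <- expand.grid(month = 1:12, year = years)
  df$value <- rnorm(nrow(df))
  for (m in 1:3) df$value[df$month == m] <- sig[match(df$year[df$month == m],
                                                      years)]
  dep <- climate_departure("moisture_index", df, range(years))
  tree <- index_series("T01", 1930L, sig)
  r <- seasonal_sensitivity(tree, dep, c("curr.Jan", "curr.Feb", "curr.Mar"),
                            c(1931, 2021))
  expect_equal(r, 1, tolerance = 1e-9)
  # sign flip negates the mean correlation
  tree_neg <- index_series("T02", 1930L, -sig)
  expect_equal(seasonal_sensitivity(tree_neg, dep,
                                    c("curr.Jan", "curr.Feb", "curr.Mar"),
                                    c(1931, 2021)), -r)
  expect_error(seasonal_sensitivity(tree, dep, "no.Such", c(1931, 2021)),
               "slot")
})

test_that("generator climate couplings are recovered with the right sign", {
  hits <- 0
  for (seed in 301:310) {
    fx <- make_sim(seed)
    deps <- make_departures(fx$climate)
    decl <- fx$sim$truth$tree_id[fx$sim$truth$group == "decline"][1]
    std <- detrend(fx$sim$bai[[decl]], "mean_line")
    r <- seasonal_sensitivity(std, deps$temperature,
                              c("curr.Dec", "curr.Jan", "curr.Feb"),
                              c(1931, 2021))
    hits <- hits + (r < 0)
  }
  expect_gte(hits, 9)   # negative DJF temperature response in >= 90%
})

test_that("the damage GAM reduces to OLS in the linear limit", {
  set.seed(74)
  damage <- seq(5, 95, length.out = 23)
  r <- -0.1 - 0.004 * damage + rnorm(23, sd = 0.02)
  fit <- damage_sensitivity_fit(r, damage)
  ols <- summary(lm(r ~ damage))$r.squared
  expect_lt(abs(fit$deviance_explained - ols), 0.02)
  expect_lt(fit$p_smooth, 0.05)
  # constant response: nothing explained
  flat <- damage_sensitivity_fit(rep(-0.2, 23), damage)
  expect_equal(flat$deviance_explained, 0)
  # monotone decreasing signal recovered over the central damage range
  r2 <- -0.5 / (1 + exp(-(damage - 50) / 12)) + rnorm(23, sd = 0.04)
  fit2 <- damage_sensitivity_fit(r2, damage)
  central <- fit2$grid[fit2$grid$damage >= quantile(damage, 0.1) &
                         fit2$grid$damage <= quantile(damage, 0.9), ]
  expect_true(all(diff(central$fit) < 1e-6))
  expect_error(damage_sensitivity_fit(r[1:5], damage[1:5]), ">= 10")
  expect_error(damage_sensitivity_fit(r, rep(40, 23)), "variance")
})
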