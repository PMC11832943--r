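test_that("P2YrsL normalization matches its closed form", {
  const <- normalize_p2yrsl(toy_rings(rep(1.4, 10)))
  expect_equal(const$values, rep(0, 9))
  two <- normalize_p2yrsl(toy_rings(c(1, 3)))
  expect_equal(two$values, log(2 * 3 / 4), tolerance = 1e-9)
  s <- toy_rings(runif(40, 0.5, 2))
  out <- normalize_p2yrsl(s)
  expect_length(out$values, 39L)
  expect_equal(out$first_year, s$first_year + 1L)
  expect_error(normalize_p2yrsl(toy_rings(c(1, 0, 1))), "log")
})

test_that("cross-dating statistics follow the r and t thresholds strictly", {
  set.seed(11)
  v <- rnorm(50)
  a <- index_series("a", 1950L, v)
  cs <- crossdate_stats(a, a)
  expect_equal(cs$r, 1)
  expect_equal(cs$t, 1e6)   # sentinel for |r| = 1
  expect_true(cs$pass)
  # strict inequality at the threshold: r = 1 does not pass r_min = 1
  expect_false(crossdate_stats(a, a, r_min = 1)$pass)
  # anti-phase toy series fails
  yr12 <- rep(c(1, -1), 6) * c(1.2, 0.8, 1.1, 0.9, 1.3, 0.7, 1.2, 0.8,
                               1.1, 0.9, 1.3, 0.7)
  b <- index_series("b", 1950L, yr12)
  c2 <- index_series("c", 1950L, -yr12)
  anti <- crossdate_stats(b, c2)
  expect_lt(anti$r, 0)
  expect_false(anti$pass)
  expect_error(crossdate_stats(a, index_series("d", 2030L, rnorm(20))),
               "overlap")
})

test_that("mean-line detrending is exact and ratio-preserving", {
  idx <- detrend(toy_rings(c(2, 4, 6)), "mean_line")
  expect_equal(idx$values, c(0.5, 1.0, 1.5))
  # relative year-to-year ratios preserved exactly
  w <- runif(30, 0.5, 3)
  out <- detrend(toy_rings(w), "mean_line")$values
  expect_equal(out[-1] / out[-30], w[-1] / w[-30], tolerance = 1e-12)
})

test_that("the 32-yr spline removes low frequencies more than high", {
  t <- 1:200
  low <- 10 + sin(2 * pi * t / 64)   # below the cutoff frequency
  high <- 10 + sin(2 * pi * t / 8)   # above the cutoff frequency
  res_low <- detrend(toy_rings(low), "spline32")$values - 1
  res_high <- detrend(toy_rings(high), "spline32")$values - 1
  trim <- 20:180   # avoid boundary effects
  amp_low <- max(abs(res_low[trim]))
  amp_high <- max(abs(res_high[trim]))
  expect_lt(amp_low, 0.25 * amp_high)
  # closed-form response at the cutoff is 1/2: a 32-yr sinusoid keeps
  # about half its amplitude in the index
  mid <- 10 + sin(2 * pi * t / 32)
  amp_mid <- max(abs(detrend(toy_rings(mid), "spline32")$values[trim] - 1))
  expect_equal(amp_mid * 10, 0.5, tolerance = 0.1)
  # constant series maps to an all-ones index under either method
  for (m in c("spline32", "mean_line")) {
    expect_equal(detrend(toy_rings(rep(2, 40)), m)$values, rep(1, 40))
  }
})

test_that("the biweight mean is robust and respects symmetry", {
  expect_equal(biweight_mean(c(0.8, 1.0, 1.2)), 1.0)
  expect_equal(biweight_mean(c(1, 1, 1, 1, 100)), 1, tolerance = 0.01)
  expect_equal(biweight_mean(3.7), 3.7)
  # an outlier barely moves the estimate while the mean jumps
  x <- c(0.9, 1.0, 1.05, 1.1, 0.95, 20)
  expect_lt(abs(biweight_mean(x) - 1), 0.1)
  expect_gt(mean(x), 4)
})

test_that("EPS closed form and monotonicity behave as the theory demands", {
  expect_equal(eps_from_rbar(10, 0), 0)
  # monotone increasing in both n and rbar; -> 1 as n grows
  rb <- seq(0.1, 0.9, by = 0.2)
  for (r in rb) {
    e <- eps_from_rbar(2:200, r)
    expect_true(all(diff(e) > 0))
    expect_gt(eps_from_rbar(1e6, r), 0.999)   # EPS -> 1 as n grows
  }
  for (n in c(5, 23, 60)) {
    expect_true(all(diff(eps_from_rbar(n, rb)) > 0))
  }
})

test_that("rbar_and_eps estimates the mean pairwise correlation", {
  set.seed(21)
  common <- rnorm(80)
  idx <- lapply(1:8, function(i) {
    index_series(paste0("s", i), 1940L, common + rnorm(80, sd = 1))
  })
  st <- rbar_and_eps(idx, c(1940, 2019))
  # common share is 1/2 of variance -> expected pairwise r = 0.5
  expect_equal(st$rbar, 0.5, tolerance = 0.1)
  expect_equal(st$eps, eps_from_rbar(st$n_eff, st$rbar))
  expect_equal(st$n_pairs, choose(8, 2))
  # identical series: rbar = eps = 1
  same <- rbar_and_eps(idx[c(1, 1)], c(1940, 2019))
  expect_equal(same$rbar, 1)
  expect_equal(same$eps, 1)
  expect_error(rbar_and_eps(idx[1], c(1940, 2019)), "at least 2")
  short <- lapply(1:2, function(i) index_series(paste0("t", i), 1940L,
                                                rnorm(10)))
  expect_error(rbar_and_eps(short, c(1940, 2019)), "common years")
})

test_that("chronology building is robust, order-invariant and noise-averaging", {
  set.seed(31)
  base <- index_series("b", 1900L, runif(60, 0.5, 1.5))
  same <- lapply(1:5, function(i) {
    index_series(paste0("c", i), 1900L, base$values)
  })
  ch <- build_chronology(same)
  expect_equal(ch$value, base$values)
  expect_equal(ch$sample_depth, rep(5L, 60))
  expect_equal(attr(ch, "reliable_from"), 1900L)
  # betweenness for two level-offset series
  lo <- index_series("lo", 1900L, base$values - 0.2)
  hi <- index_series("hi", 1900L, base$values + 0.3)
  mid <- build_chronology(list(lo, hi))
  expect_true(all(mid$value > lo$values & mid$value < hi$values))
  # order invariance
  series <- lapply(1:10, function(i) {
    index_series(paste0("s", i), 1900L, base$values + rnorm(60, sd = 0.4))
  })
  expect_equal(build_chronology(series)$value,
               build_chronology(rev(series))$value)
  # the chronology tracks the common signal better than any single series
  chron <- build_chronology(series)
  r_single <- vapply(series, function(s) cor(s$values, base$values),
                     numeric(1))
  expect_gt(cor(chron$value, base$values), max(r_single))
})
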