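test_that("simulation is bit-reproducible from (params, seed)", {
  sp <- stand_params(seed = 9L)
  c1 <- simulate_climate(1900:2021, sp, seed = 9)
  c2 <- simulate_climate(1900:2021, sp, seed = 9)
  expect_identical(c1$tables, c2$tables)
  expect_identical(c1$anomalies, c2$anomalies)
  sp2 <- stand_params(seed = 9L, series_length = 100L, length_spread = 10L)
  s1 <- simulate_stand(sp2, c1)
  s2 <- simulate_stand(sp2, c1)
  expect_identical(lapply(s1$cores, `[[`, "widths"),
                   lapply(s2$cores, `[[`, "widths"))
  expect_identical(s1$trees$crown_damage, s2$trees$crown_damage)
  expect_identical(s1$truth, s2$truth)
})

test_that("simulated climate matches the site climatology", {
  sp <- stand_params(seed = 10L)
  clim <- simulate_climate(1922:2021, sp, seed = 10)
  p_tabs <- clim$tables[grepl("precipitation", names(clim$tables))]
  annual <- vapply(p_tabs, function(tab) {
    mean(tapply(tab$value, tab$year, sum))
  }, numeric(1))
  expect_lt(abs(mean(annual) - 754) / 754, 0.10)
  t_tab <- clim$tables[[grep("temperature", names(clim$tables))[1]]]
  expect_lt(abs(mean(t_tab$value[t_tab$year < 1976]) - 5.2), 1.0)
  # southern hemisphere: January is the warmest month on average
  monthly <- tapply(t_tab$value, t_tab$month, mean)
  expect_equal(unname(which.max(monthly)), 1L)
})

test_that("stations share the regional anomaly (r > 0.7 by construction)", {
  sp <- stand_params(seed = 11L)
  clim <- simulate_climate(1922:2021, sp, seed = 11)
  z <- lapply(clim$tables, standardize_station, reference = c(1992, 2021))
  r_t <- cor(z[["T01.temperature"]]$value, z[["T02.temperature"]]$value)
  r_p <- cor(z[["P01.precipitation"]]$value, z[["P02.precipitation"]]$value)
  expect_gt(r_t, 0.7)
  expect_gt(r_p, 0.7)
})

test_that("ring geometry inverts: bai_from_dbh recovers the generated BAI", {
  fx <- make_sim(12, length_spread = 20L)
  for (id in fx$sim$trees$tree_id[1:5]) {
    tree_rings <- merge_cores_to_tree(
      lapply(fx$sim$cores[grep(id, names(fx$sim$cores))], identity))
    # exact inversion needs the noise-free widths; rebuild them from truth
    true_bai <- fx$sim$bai[[id]]
    r <- sqrt(2^2 + cumsum(true_bai$bai) / pi)
    rs <- ring_series(id, id, true_bai$first_year, diff(c(2, r)))
    back <- bai_from_dbh(rs, fx$sim$trees$dbh[fx$sim$trees$tree_id == id])
    expect_lt(max(abs(back$bai - true_bai$bai) / true_bai$bai), 0.005)
  }
})

test_that("the declining group halves its growth by construction", {
  # deterministic sub-case: no noise, no climate, no stress events
  sp <- stand_params(seed = 13L, noise_sd = 0, core_noise_sd = 0,
                     indiv_ar_sd = 0, stand_sd = 0, stress_rate = 0,
                     beta_t = 0, beta_p = 0, beta_mi = 0,
                     slope_spread = 0, length_spread = 0L)
  clim <- simulate_climate(1870:2021, sp, seed = 13)
  sim <- simulate_stand(sp, clim)
  g <- sim$truth$group
  decl <- sim$bai[[sim$truth$tree_id[g == "decline"][1]]]
  div_idx <- sp$divergence_year
  expect_equal(decl$bai[length(decl$bai)] / decl$bai[div_idx],
               exp(-sp$decline_rate * 80), tolerance = 0.02)
  expect_equal(exp(-sp$decline_rate * 80), 0.5, tolerance = 1e-9)
  # stable trees keep rising
  stab <- sim$bai[[sim$truth$tree_id[g == "stable"][1]]]
  expect_gt(stab$bai[length(stab$bai)], stab$bai[div_idx])
})

test_that("a degenerate stand with no variability collapses onto one mode", {
  sp <- stand_params(seed = 14L, noise_sd = 0, core_noise_sd = 0,
                     indiv_ar_sd = 0, stand_sd = 0, stress_rate = 0,
                     beta_t = 0, beta_p = 0, beta_mi = 0,
                     slope_spread = 0, length_spread = 0L,
                     decline_group_fraction = 0)
  clim <- simulate_climate(1870:2021, sp, seed = 14)
  sim <- simulate_stand(sp, clim)
  b <- vapply(sim$bai, `[[`, numeric(sp$series_length), "bai")
  expect_equal(max(apply(b, 1, sd)), 0, tolerance = 1e-10)
  m <- bai_matrix(sim$bai, c(2021 - sp$series_length + 1, 2021))
  expect_equal(pca_growth_modes(m)$var_explained[1], 1, tolerance = 1e-9)
})

test_that("crown damage follows the field protocol and the damage model", {
  fx <- make_sim(15)
  d <- fx$sim$trees$crown_damage
  expect_true(all(d >= 0 & d <= 100))
  expect_true(all(d %% 5 == 0))   # 5-percent classes
  g <- fx$sim$truth$group
  expect_gt(mean(d[g == "decline"]), mean(d[g == "stable"]))
  # decoupled damage is independent of the group
  fx0 <- make_sim(15, couple_damage = FALSE)
  expect_true(all(fx0$sim$trees$crown_damage %% 5 == 0))
})

test_that("generator guards impossible parameter combinations", {
  expect_error(stand_params(seed = 1, series_length = 50L), ">= 80")
  expect_error(stand_params(), "mandatory")
  sp <- stand_params(seed = 16L)
  clim <- simulate_climate(1922:2021, sp, seed = 16)  # too short for 240-yr trees
  expect_error(simulate_climate(2000:2021, sp, seed = 1), ">= 80")
  expect_error(simulate_stand(sp, clim), "cover")
})
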