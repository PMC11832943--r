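# fixtures are built in code: no data files

# a short deterministic ring series
toy_rings <- function(widths, first_year = 2000L, id = "T01a",
                      tree = "T01") {
  ring_series(id, tree, first_year, widths)
}

# default synthetic stand + climate (smallish, deterministic)
make_sim <- function(seed = 1L, ...) {
  sp <- stand_params(seed = seed, ...)
  clim <- simulate_climate(1770:2021, sp, seed = seed)
  sim <- simulate_stand(sp, clim, seed = seed + 1L)
  list(params = sp, climate = clim, sim = sim)
}

# regional climate departures from a sim_climate
make_departures <- function(clim, reference = c(1992, 2021)) {
  deps <- lapply(clim$tables, standardize_station, reference = reference)
  is_t <- vapply(deps, function(d) attr(d, "variable") == "temperature",
                 logical(1))
  temp <- regional_mean(deps[is_t])
  precip <- regional_mean(deps[!is_t])
  list(temperature = temp, precipitation = precip,
       moisture_index = moisture_index(precip, temp))
}

# accuracy of a PCA group assignment against generator truth
assignment_accuracy <- function(sim) {
  per <- c(max(vapply(sim$bai, function(b) min(years(b)), numeric(1))),
           max(vapply(sim$bai, function(b) max(years(b)), numeric(1))))
  m <- bai_matrix(sim$bai, per)
  a <- assign_to_mode(m, pca_growth_modes(m))
  g <- sim$truth$group[match(a$tree_id, sim$truth$tree_id)]
  acc1 <- mean((a$label == "PC1") == (g == "stable"))
  max(acc1, 1 - acc1)
}

# group BAI chronology taus over a period
group_taus <- function(sim, period = c(1941, 2021)) {
  g <- sim$truth$group
  st <- build_chronology(sim$bai[sim$truth$tree_id[g == "stable"]], 1L)
  de <- build_chronology(sim$bai[sim$truth$tree_id[g == "decline"]], 1L)
  c(stable = mann_kendall(st, period)$tau,
    decline = mann_kendall(de, period)$tau)
}

# per-tree DJF temperature sensitivity and its damage GAM p-value
damage_gam_p <- function(seed, couple = TRUE) {
  fx <- make_sim(seed, couple_damage = couple)
  deps <- make_departures(fx$climate)
  std_bai <- lapply(fx$sim$bai, detrend, method = "mean_line")
  r <- vapply(std_bai, seasonal_sensitivity, numeric(1),
              deps$temperature, c("curr.Dec", "curr.Jan", "curr.Feb"),
              c(1931, 2021))
  damage_sensitivity_fit(r, fx$sim$trees$crown_damage)$p_smooth
}
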