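#' Parameters of the synthetic stand generator
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' xeric old-growth southern-beech stand of 23 trees (2 cores each), ring
#' series of 140+ years ending in 2021, a minority subgroup (6 of 23
#' trees) whose basal area increment diverges to an exponential decline 80
#' years before the end of the record (halving growth by the final year),
#' growth forced negatively by December--February temperature and
#' positively by the January--March moisture index, and visually assessed
#' crown damage (5-percent classes) that is higher in the declining group
#' and increases with the tree's temperature-sensitivity amplitude.
#'
#' @param n_trees Number of trees (default 23).
#' @param cores_per_tree Cores per tree (default 2).
#' @param series_length Minimum series length in years (default 140).
#' @param length_spread Extra series length, spread uniformly across trees
#'   (default 100; series lengths then span 140--240 yr).
#' @param last_year Calendar year of the last ring (default 2021).
#' @param bai_base,bai_slope Age trend `J(t) = bai_base + bai_slope * t`
#'   (mm^2 yr^-1; defaults 50 and 4.5): with a roughly constant ring
#'   width on an ever-larger radius, the basal area increment of an
#'   undisturbed dominant tree keeps rising about linearly for centuries,
#'   so healthy trees carry a persistent positive BAI trend. Each tree
#'   draws its own slope uniformly from `bai_slope * (1 +/-
#'   slope_spread)`, so age-trend shapes differ across the naturally
#'   regenerated mosaic.
#' @param slope_spread Relative spread of the per-tree trend slope
#'   (default 0.4).
#' @param divergence_year Ring index at which the declining group departs
#'   from the shared trajectory (default `series_length - 80`).
#' @param decline_group_fraction Fraction of declining trees (default 6/23).
#' @param decline_rate Fractional BAI loss per year after divergence
#'   (default `log(2)/80`: growth halves over the 80 declining years).
#' @param noise_sd Lognormal sd of multiplicative year-to-year growth
#'   noise (default 0.2).
#' @param stand_sd,stand_phi Stand-wide common year effect (lognormal
#'   AR(1); defaults sd 0.25, lag-1 coefficient 0.3) shared equally by all
#'   trees: weather influences beyond the three modeled seasonal
#'   couplings (late frost, snow-cover duration, cloudiness) that give
#'   real stands their strong common high-frequency signal.
#' @param indiv_ar_sd,indiv_ar_phi Per-tree low-frequency growth
#'   modulation (lognormal AR(1); defaults sd 0.25, lag-1 coefficient
#'   0.9): individual disturbance and micro-site effects that detrending
#'   is designed to remove.
#' @param stress_rate,stress_depth,stress_recovery Shared stress episodes
#'   of the declining group after divergence: events at Poisson rate
#'   `stress_rate` per year (default 1/12), each an immediate log-scale
#'   growth drop drawn uniformly from `stress_depth` (default 0.3--0.9)
#'   that decays back over `stress_recovery` years (default 6). These
#'   synchronous damage episodes bind the declining trees into a common
#'   trajectory; the permanent part of the damage is carried by
#'   `decline_rate`. After divergence a declining tree's juvenile trend is
#'   frozen at its divergence-year value (a damaged crown no longer
#'   expands), so the declining group also stops sharing the stand's
#'   continued slow rise.
#' @param core_noise_sd Lognormal sd of per-core measurement noise
#'   (default 0.03).
#' @param beta_t,beta_p,beta_mi Stand-level climate sensitivities per sd of
#'   DJF temperature, June--July precipitation and JFM moisture index
#'   (defaults -0.3, 0.1, 0.3).
#' @param sens_range_stable,sens_range_decline Ranges of the per-tree
#'   sensitivity multiplier for stable and declining trees.
#' @param damage_base,damage_gain,damage_slope,damage_noise_sd Crown-damage
#'   model `damage = base + gain * is_declining + slope * |beta_t_i| +
#'   noise`, truncated to \[0, 100\] and rounded to 5-percent classes.
#' @param couple_damage If `FALSE`, damage is pure `base + noise`,
#'   independent of group and sensitivity (for specificity checks).
#' @param warm_start First year of the regional warming/drying trend
#'   (default 1976, the documented regime shift).
#' @param warm_trend_sd Temperature-anomaly rise from `warm_start` to the
#'   last simulated year, in sd units (default 1.0).
#' @param dry_trend_sd Precipitation-anomaly fall over the same span, in
#'   sd units (default 0.4).
#' @param seed RNG seed (mandatory).
#' @return List of class `stand_params`.
#' @export
stand_params <- function(n_trees = 23L, cores_per_tree = 2L,
                         series_length = 140L, length_spread = 100L,
                         last_year = 2021L,
                         bai_base = 50, bai_slope = 4.5, slope_spread = 0.4,
                         divergence_year = series_length - 80L,
                         decline_group_fraction = 6 / 23,
                         decline_rate = log(2) / 80,
                         noise_sd = 0.2,
                         stand_sd = 0.25, stand_phi = 0.3,
                         indiv_ar_sd = 0.25, indiv_ar_phi = 0.9,
                         stress_rate = 1 / 12, stress_depth = c(0.3, 0.9),
                         stress_recovery = 6,
                         core_noise_sd = 0.03,
                         beta_t = -0.3, beta_p = 0.1, beta_mi = 0.3,
                         sens_range_stable = c(0.05, 0.55),
                         sens_range_decline = c(1.0, 2.0),
                         damage_base = 10, damage_gain = 35,
                         damage_slope = 100, damage_noise_sd = 10,
                         couple_damage = TRUE,
                         warm_start = 1976L, warm_trend_sd = 1.0,
                         dry_trend_sd = 0.4,
                         seed) {
  if (series_length < 80L) stop("series_length must be >= 80")
  stopifnot(decline_group_fraction >= 0, decline_group_fraction <= 1,
            noise_sd >= 0, cores_per_tree >= 1)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  structure(as.list(environment()), class = "stand_params")
}

#' Simulate monthly station climate
#'
#' Nine virtual stations (3 recording temperature, 6 precipitation) around
#' a cool-temperate seasonal climatology (mean annual temperature 5.2 deg
#' C with midsummer in January, annual precipitation 754 mm falling mostly
#' in winter). A shared regional AR(1) monthly anomaly (unit sd, lag-1
#' coefficient 0.3) drives all stations of a variable, plus independent
#' station noise sized so that inter-station anomaly correlation is 0.8 by
#' construction.
#'
#' @param years Integer vector of calendar years to simulate.
#' @param params A [stand_params()] (reserved for future climatology
#'   knobs).
#' @param seed RNG seed.
#' @return List of class `sim_climate`: `tables` (list of
#'   [climate_table()]), `anomalies` (data.frame `year`, `month`, `t_z`,
#'   `p_z` with the shared unit-sd regional anomalies — the generator's
#'   ground truth).
#' @export
simulate_climate <- function(years, params = stand_params(seed = 1L), seed) {
  if (length(years) < 80L) stop("need >= 80 years of climate")
  set.seed(seed)
  years <- sort(as.integer(years))
  n_mon <- length(years) * 12L
  # midsummer (January) peak; Nov-Feb means ~10.8 degC / ~75 mm total
  month_angle <- 2 * pi * (0:11) / 12
  t_clim <- 5.2 + 6.93 * cos(month_angle)
  p_clim <- 62.83 - 54.6 * cos(month_angle)
  ar1 <- function(n, phi = 0.3) {
    as.numeric(stats::arima.sim(list(ar = phi), n,
                                sd = sqrt(1 - phi^2)))
  }
  grid <- data.frame(year = rep(years, each = 12L), month = rep(1:12, length(years)))
  # post-1976 regional warming and slight drying, in anomaly sd units
  ramp <- pmin(1, pmax(0, (grid$year - params$warm_start) /
                            (max(years) - params$warm_start)))
  t_z <- ar1(n_mon) + params$warm_trend_sd * ramp
  p_z <- ar1(n_mon) - params$dry_trend_sd * ramp
  anomalies <- cbind(grid, t_z = t_z, p_z = p_z)
  tables <- list()
  for (s in 1:3) {
    noise <- stats::rnorm(n_mon, 0, 0.6)
    v <- t_clim[grid$month] + 1.2 * t_z + noise
    id <- sprintf("T%02d", s)
    tables[[paste0(id, ".temperature")]] <-
      climate_table(id, "temperature",
                    data.frame(year = grid$year, month = grid$month, value = v))
  }
  for (s in 1:6) {
    noise <- stats::rnorm(n_mon, 0, 0.175)
    v <- pmax(0, p_clim[grid$month] * (1 + 0.35 * p_z + noise))
    id <- sprintf("P%02d", s)
    tables[[paste0(id, ".precipitation")]] <-
      climate_table(id, "precipitation",
                    data.frame(year = grid$year, month = grid$month, value = v))
  }
  structure(list(tables = tables, anomalies = anomalies),
            class = "sim_climate")
}

# ground-truth seasonal forcings per growth year from the shared anomalies:
# DJF temperature (Dec y-1, Jan/Feb y), JFM moisture index (Jan-Mar y),
# June-July precipitation (winter snow, year y-1... the winter within the
# 19-month window of growth year y is May-Sep of y-1)
season_forcings <- function(anomalies, growth_years) {
  key <- paste(anomalies$year, anomalies$month)
  pick <- function(yrs, mons, col) {
    v <- anomalies[[col]][match(paste(yrs, mons), key)]
    mean(v)
  }
  t_djf <- vapply(growth_years, function(y) {
    pick(c(y - 1, y, y), c(12, 1, 2), "t_z")
  }, numeric(1))
  mi_jfm <- vapply(growth_years, function(y) {
    pick(rep(y, 3), 1:3, "p_z") - pick(rep(y, 3), 1:3, "t_z")
  }, numeric(1))
  p_jj <- vapply(growth_years, function(y) {
    pick(rep(y - 1, 2), 6:7, "p_z")
  }, numeric(1))
  data.frame(year = growth_years, t_djf = t_djf, mi_jfm = mi_jfm,
             p_jj = p_jj)
}

#' Simulate a stand of ring-width series with ground truth
#'
#' Per tree, the expected BAI is
#' `J(t) * G_i(t) * exp(beta_t_i * T_DJF + beta_p_i * P_JJ + beta_mi_i *
#' MI_JFM)` times lognormal noise, where `J` is the juvenile trend, `G_i`
#' the group trend multiplier (1 for stable trees; exponential decline
#' after the divergence year for the declining minority), and the climate
#' forcings are the shared regional anomalies in sd units. Ring widths are
#' back-converted through the ring geometry (`r_t = sqrt(r0^2 +
#' sum(BAI)/pi)` with a 2 mm pith offset) so that [bai_from_dbh()] at the
#' recorded DBH inverts the construction exactly. Cores add small
#' multiplicative measurement noise. Crown damage follows the damage model
#' of [stand_params()].
#'
#' @param params A [stand_params()].
#' @param climate A `sim_climate` from [simulate_climate()] covering all
#'   ring years.
#' @param seed RNG seed (defaults to `params$seed`).
#' @return List of class `sim_stand`: `cores` (list of [ring_series()]),
#'   `trees` (`tree_records` with dbh, height, crown_damage, min_age,
#'   neighbors, hegyi), `truth` (data.frame with group, per-tree
#'   sensitivities, true Tau-relevant trend factor), `bai` (list of true
#'   [bai_series()]), `params`.
#' @export
simulate_stand <- function(params, climate, seed = params$seed) {
  stopifnot(inherits(params, "stand_params"), inherits(climate, "sim_climate"))
  set.seed(seed)
  p <- params
  n <- p$n_trees
  ids <- sprintf("T%02d", seq_len(n))
  n_decline <- round(p$decline_group_fraction * n)
  group <- rep("stable", n)
  if (n_decline > 0) group[sample.int(n, n_decline)] <- "decline"
  # per-tree series length and years
  extra <- if (p$length_spread > 0) {
    sample.int(p$length_spread + 1L, n, replace = TRUE) - 1L
  } else rep(0L, n)
  len <- p$series_length + extra
  need_years <- (p$last_year - max(len) - 1L):p$last_year
  if (!all(need_years %in% unique(climate$anomalies$year))) {
    stop("climate does not cover all ring years")
  }
  smult <- numeric(n)
  for (i in seq_len(n)) {
    rng <- if (!p$couple_damage) {
      range(c(p$sens_range_stable, p$sens_range_decline))
    } else if (group[i] == "decline") p$sens_range_decline else p$sens_range_stable
    smult[i] <- stats::runif(1, rng[1], rng[2])
  }
  beta_t_i <- p$beta_t * smult
  beta_p_i <- p$beta_p * smult
  beta_mi_i <- p$beta_mi * smult
  fc_all <- season_forcings(climate$anomalies,
                            (p$last_year - max(len) + 1L):p$last_year)
  ar1_log <- function(n, phi, sd_target) {
    if (sd_target <= 0 || n < 2L) return(rep(0, n))
    as.numeric(stats::arima.sim(list(ar = phi), n,
                                sd = sd_target * sqrt(1 - phi^2)))
  }
  # shared stress episodes of the declining group, indexed by calendar
  # year: Poisson-timed log-scale drops after divergence, each decaying
  # back over the recovery time
  div_cal <- p$last_year - (p$series_length - p$divergence_year)
  stress_years <- fc_all$year
  stand_log <- ar1_log(length(stress_years), p$stand_phi, p$stand_sd)
  stress_log <- rep(0, length(stress_years))
  post <- stress_years > div_cal
  n_events <- stats::rpois(1, p$stress_rate * sum(post))
  if (n_events > 0) {
    ev_year <- sort(sample(stress_years[post], n_events))
    ev_depth <- stats::runif(n_events, p$stress_depth[1], p$stress_depth[2])
    for (k in seq_len(n_events)) {
      dt <- stress_years - ev_year[k]
      hit <- dt >= 0
      stress_log[hit] <- stress_log[hit] -
        ev_depth[k] * exp(-dt[hit] / p$stress_recovery)
    }
  }
  cores <- list()
  bai_list <- list()
  trees <- data.frame(tree_id = ids, dbh = NA_real_, height = NA_real_,
                      crown_damage = NA_real_, min_age = len,
                      stringsAsFactors = FALSE)
  neighbors <- vector("list", n)
  for (i in seq_len(n)) {
    li <- len[i]
    yrs <- (p$last_year - li + 1L):p$last_year
    fc <- fc_all[match(yrs, fc_all$year), ]
    t_idx <- seq_len(li)
    slope_i <- p$bai_slope * stats::runif(1, 1 - p$slope_spread,
                                          1 + p$slope_spread)
    J <- p$bai_base + slope_i * t_idx
    G <- rep(1, li)
    if (group[i] == "decline") {
      div <- li - (p$series_length - p$divergence_year)
      after <- t_idx > div
      G[after] <- exp(-p$decline_rate * (t_idx[after] - div))
      # crown damage halts canopy expansion: trend frozen at divergence
      J[after] <- J[max(div, 1L)]
      G <- G * exp(stress_log[match(yrs, stress_years)])
    }
    clim_mult <- exp(beta_t_i[i] * fc$t_djf + beta_p_i[i] * fc$p_jj +
                       beta_mi_i[i] * fc$mi_jfm)
    indiv <- exp(ar1_log(li, p$indiv_ar_phi, p$indiv_ar_sd))
    stand_mult <- exp(stand_log[match(yrs, stress_years)])
    noise <- if (p$noise_sd > 0) {
      exp(stats::rnorm(li, -p$noise_sd^2 / 2, p$noise_sd))
    } else rep(1, li)
    bai <- J * G * clim_mult * stand_mult * indiv * noise
    if (any(bai <= 0)) stop("parameters drove BAI <= 0 for tree ", ids[i])
    r0 <- 2
    r <- sqrt(r0^2 + cumsum(bai) / pi)
    w <- diff(c(r0, r))
    if (any(w <= 0)) stop("parameters drove ring width <= 0 for tree ", ids[i])
    trees$dbh[i] <- 2 * r[li]
    bai_list[[ids[i]]] <- bai_series(ids[i], yrs[1], bai)
    for (k in seq_len(p$cores_per_tree)) {
      wk <- if (p$core_noise_sd > 0) {
        w * exp(stats::rnorm(li, 0, p$core_noise_sd))
      } else w
      cid <- paste0(ids[i], letters[k])
      cores[[cid]] <- ring_series(cid, ids[i], yrs[1], wk)
    }
  }
  trees$height <- pmin(14, 12 * (trees$dbh / max(trees$dbh))^0.5 *
                         exp(stats::rnorm(n, 0, 0.05)))
  is_decline <- as.numeric(group == "decline")
  damage <- if (p$couple_damage) {
    p$damage_base + p$damage_gain * is_decline +
      p$damage_slope * abs(beta_t_i) +
      stats::rnorm(n, 0, p$damage_noise_sd)
  } else {
    p$damage_base + 25 + stats::rnorm(n, 0, 2.5 * p$damage_noise_sd)
  }
  trees$crown_damage <- pmin(100, pmax(0, round(damage / 5) * 5))
  for (i in seq_len(n)) {
    nb <- data.frame(
      dbh = stats::rlnorm(5, log(mean(trees$dbh)) - 0.045, 0.3),
      dist = stats::runif(5, 1.5, 6))
    neighbors[[i]] <- nb
  }
  trees$neighbors <- neighbors
  trees$hegyi <- vapply(seq_len(n), function(i) {
    hegyi_index(trees$dbh[i], trees$neighbors[[i]])
  }, numeric(1))
  class(trees) <- c("tree_records", "data.frame")
  truth <- data.frame(tree_id = ids, group = group,
                      beta_t = beta_t_i, beta_p = beta_p_i,
                      beta_mi = beta_mi_i, sens_mult = smult,
                      stringsAsFactors = FALSE)
  structure(list(cores = cores, trees = trees, truth = truth,
                 bai = bai_list, params = p),
            class = "sim_stand")
}
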