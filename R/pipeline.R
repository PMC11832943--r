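#' Default pipeline run configuration
#'
#' All analysis periods, thresholds and seeds in one list. Input paths are
#' optional: when absent, the pipeline runs on a synthetic stand generated
#' with [stand_params()] under `seed`.
#'
#' @param seed RNG seed for the whole run (generator and bootstrap).
#' @param rwl_path,rings_csv_path Optional ring-width input (Tucson or
#'   long CSV; supply one).
#' @param metadata_path Optional tree metadata CSV.
#' @param climate_path Optional station climate CSV.
#' @param pca_period PCA span (`NULL` = common overlap of all trees).
#' @param trend_period Mann-Kendall span (default 1941--2021).
#' @param climate_period Climate-correlation span (default 1931--2021).
#' @param reference_period Climate z-score reference (default 1992--2021).
#' @param recent_window Recent-growth window (default 2002--2021).
#' @param detrend_method Standardization used for the climate-sensitivity
#'   chronologies (default `"mean_line"`).
#' @param n_boot Bootstrap draws for climate correlations (default 1000).
#' @param eps_threshold EPS adequacy threshold (default 0.85).
#' @param crossdate_r,crossdate_t Cross-dating acceptance thresholds.
#' @param min_depth Minimum sample depth for the reliable chronology span.
#' @param sim Optional [stand_params()] overriding the default generator
#'   settings (its seed is replaced by `seed`).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       rwl_path = NULL, rings_csv_path = NULL,
                       metadata_path = NULL, climate_path = NULL,
                       pca_period = NULL,
                       trend_period = c(1941L, 2021L),
                       climate_period = c(1931L, 2021L),
                       reference_period = c(1992L, 2021L),
                       recent_window = c(2002L, 2021L),
                       detrend_method = "mean_line",
                       n_boot = 1000L,
                       eps_threshold = 0.85,
                       crossdate_r = 0.32, crossdate_t = 3.5,
                       min_depth = 5L,
                       sim = NULL) {
  cfg <- as.list(environment())
  for (p in c("trend_period", "climate_period", "reference_period",
              "recent_window")) {
    if (cfg[[p]][1] > cfg[[p]][2]) stop(p, " is not well-ordered")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON or YAML
#'
#' The file holds any subset of the [run_config()] fields; unspecified
#' fields keep their defaults.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs")
    }
    yaml::read_yaml(path)
  } else stop("unsupported config format: ", ext)
  do.call(run_config, raw)
}

#' Run the full growth-decline analysis pipeline
#'
#' Executes input/simulation, core merging, BAI reconstruction,
#' cross-dating validation, spline and mean-line standardization,
#' chronology building with EPS/Rbar, PCA growth-trajectory
#' classification, group trait tests, Mann-Kendall trends with
#' crown-damage thresholds, climate departures and moisture index,
#' bootstrapped monthly climate-growth correlations, and the GAM of
#' seasonal sensitivity versus crown damage. When `outdir` is given, all
#' module outputs (CSV) plus a JSON run report are written there.
#'
#' @param config A [run_config()], or a path accepted by
#'   [read_run_config()]; `NULL` uses the defaults (synthetic stand).
#' @param outdir Optional output directory.
#' @return The run report, a nested list (invisibly also written to
#'   `outdir/report.json`).
#' @export
run_pipeline <- function(config = NULL, outdir = NULL) {
  if (is.null(config)) config <- run_config()
  if (is.character(config)) config <- read_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- inputs ---------------------------------------------------------
  inputs <- stage("ringio", {
    if (!is.null(config$rwl_path) || !is.null(config$rings_csv_path)) {
      cores <- if (!is.null(config$rwl_path)) {
        read_rwl(config$rwl_path)
      } else read_rings_csv(config$rings_csv_path)
      trees <- read_tree_metadata(config$metadata_path)
      clim_tables <- read_climate(config$climate_path)
      list(cores = cores, trees = trees, clim_tables = clim_tables)
    } else {
      sp <- config$sim
      if (is.null(sp)) sp <- stand_params(seed = config$seed)
      sp$seed <- config$seed
      span <- (sp$last_year - sp$series_length - sp$length_spread - 2L):sp$last_year
      clim <- simulate_climate(span, sp, seed = config$seed)
      sim <- simulate_stand(sp, clim, seed = config$seed + 1L)
      list(cores = sim$cores, trees = sim$trees,
           clim_tables = clim$tables, sim = sim)
    }
  })
  truth <- if (!is.null(inputs$sim)) inputs$sim$truth else NULL
  trees <- inputs$trees

  # ---- merge cores, summaries, BAI ------------------------------------
  tree_series <- stage("ringio", {
    by_tree <- split(inputs$cores,
                     vapply(inputs$cores, function(s) s$tree_id, character(1)))
    lapply(by_tree, merge_cores_to_tree)
  })
  tree_series <- tree_series[trees$tree_id]
  summaries <- lapply(tree_series, series_summaries)
  trees$min_age <- vapply(summaries, `[[`, numeric(1), "min_age")
  trees$mean_rwl <- vapply(summaries, `[[`, numeric(1), "mean_rwl")
  if (is.null(trees$hegyi)) {
    trees$hegyi <- vapply(seq_len(nrow(trees)), function(i) {
      hegyi_index(trees$dbh[i], trees$neighbors[[i]])
    }, numeric(1))
  }
  bai_list <- stage("growth", {
    out <- lapply(trees$tree_id, function(id) {
      bai_from_dbh(tree_series[[id]], trees$dbh[trees$tree_id == id])
    })
    names(out) <- trees$tree_id
    out
  })

  # ---- cross-dating validation ---------------------------------------
  crossdating <- stage("chronology", {
    norm <- lapply(inputs$cores, normalize_p2yrsl)
    yrs <- range(unlist(lapply(norm, years)))
    m <- series_matrix(norm, yrs[1]:yrs[2])
    res <- lapply(seq_along(norm), function(j) {
      master_v <- rowMeans(m[, -j, drop = FALSE], na.rm = TRUE)
      ok <- is.finite(master_v)
      span <- range((yrs[1]:yrs[2])[ok])
      mv <- master_v[(yrs[1]:yrs[2]) >= span[1] & (yrs[1]:yrs[2]) <= span[2]]
      master <- index_series("master", span[1], mv, "p2yrsl")
      crossdate_stats(norm[[j]], master,
                      r_min = config$crossdate_r, t_min = config$crossdate_t)
    })
    names(res) <- names(norm)
    res
  })
  n_pass <- sum(vapply(crossdating, `[[`, logical(1), "pass"))

  # ---- chronologies and signal strength ------------------------------
  rwi <- lapply(tree_series, detrend, method = "spline32")
  site_chron_rwi <- build_chronology(rwi, min_depth = config$min_depth)
  site_chron_bai <- build_chronology(bai_list, min_depth = config$min_depth)
  stats_period <- c(attr(site_chron_rwi, "reliable_from"),
                    max(site_chron_rwi$year))
  site_stats <- stage("chronology",
                      rbar_and_eps(rwi, stats_period))

  # ---- PCA growth modes ----------------------------------------------
  pca_period <- config$pca_period
  if (is.null(pca_period)) {
    pca_period <- c(max(vapply(bai_list, function(b) min(years(b)), numeric(1))),
                    min(vapply(bai_list, function(b) max(years(b)), numeric(1))))
  }
  modes <- stage("trajectories", {
    pca_growth_modes(bai_matrix(bai_list, pca_period), k = 2L)
  })
  assignment <- assign_to_mode(bai_matrix(bai_list, pca_period), modes)
  trees$label <- assignment$label[match(trees$tree_id, assignment$tree_id)]
  group_tests <- if (length(unique(trees$label)) == 2L &&
                     min(table(trees$label)) >= 2L) {
    stage("trajectories", compare_groups(trees))
  } else NULL

  # ---- trends ---------------------------------------------------------
  group_ids <- split(trees$tree_id, trees$label)
  group_chron <- lapply(group_ids, function(ids) {
    build_chronology(bai_list[ids], min_depth = min(config$min_depth,
                                                    length(ids)))
  })
  group_stats <- lapply(names(group_chron), function(g) {
    ids <- group_ids[[g]]
    if (length(ids) < 2L) return(NULL)
    tryCatch(rbar_and_eps(rwi[ids], stats_period), error = function(e) NULL)
  })
  names(group_stats) <- names(group_chron)
  mk <- function(chron) {
    mann_kendall(chron, period = config$trend_period)
  }
  taus <- stage("trends", {
    c(list(site = mk(site_chron_bai)), lapply(group_chron, mk))
  })
  tree_trends <- lapply(bai_list, mk)
  loess_site <- stage("trends", loess_trend(site_chron_bai))
  trait_fits <- stage("trends", {
    tv <- vapply(tree_trends[trees$tree_id], `[[`, numeric(1), "tau")
    fits <- lapply(c("dbh", "height", "min_age", "crown_damage",
                     "hegyi", "mean_rwl"), function(tr) {
      trait_trend_regression(tv, trees[[tr]], tr)
    })
    names(fits) <- c("dbh", "height", "min_age", "crown_damage",
                     "hegyi", "mean_rwl")
    fits
  })
  thresholds <- stage("trends", {
    damage_thresholds(tree_trends[trees$tree_id], trees$crown_damage)
  })
  recent <- lapply(bai_list, recent_growth_stats, window = config$recent_window)

  # ---- climate --------------------------------------------------------
  climate <- stage("climate", {
    deps <- lapply(inputs$clim_tables, standardize_station,
                   reference = config$reference_period)
    is_t <- vapply(deps, function(d) attr(d, "variable") == "temperature",
                   logical(1))
    temp <- regional_mean(deps[is_t])
    precip <- regional_mean(deps[!is_t])
    list(temperature = temp, precipitation = precip,
         moisture_index = moisture_index(precip, temp),
         n_stations = c(temperature = sum(is_t),
                        precipitation = sum(!is_t)))
  })

  # ---- climate-growth sensitivity ------------------------------------
  sens <- stage("sensitivity", {
    ml_chron <- function(series_list) {
      build_chronology(lapply(series_list, detrend,
                              method = config$detrend_method),
                       min_depth = 1L)
    }
    chrons <- list(
      site.RWL = ml_chron(tree_series),
      site.BAI = ml_chron(bai_list))
    for (g in names(group_ids)) {
      chrons[[paste0(g, ".RWL")]] <- ml_chron(tree_series[group_ids[[g]]])
      chrons[[paste0(g, ".BAI")]] <- ml_chron(bai_list[group_ids[[g]]])
    }
    vars <- c("temperature", "precipitation", "moisture_index")
    out <- list()
    k <- 0L
    for (cn in names(chrons)) {
      for (v in vars) {
        k <- k + 1L
        out[[paste(cn, v, sep = ".")]] <- monthly_correlations(
          chrons[[cn]], climate[[v]], period = config$climate_period,
          n_boot = config$n_boot, seed = config$seed + 100L + k)
      }
    }
    out
  })
  damage_fits <- stage("sensitivity", {
    std_bai <- lapply(bai_list, detrend, method = "mean_line")
    aggs <- list(
      djf_temperature = list(var = "temperature",
                             slots = c("curr.Dec", "curr.Jan", "curr.Feb")),
      djf_precipitation = list(var = "precipitation",
                               slots = c("curr.Dec", "curr.Jan", "curr.Feb")),
      jfm_moisture_index = list(var = "moisture_index",
                                slots = c("curr.Jan", "curr.Feb", "curr.Mar")))
    lapply(aggs, function(a) {
      r <- vapply(std_bai[trees$tree_id], seasonal_sensitivity,
                  numeric(1), climate[[a$var]], a$slots,
                  config$climate_period)
      fit <- damage_sensitivity_fit(r, trees$crown_damage)
      list(per_tree_r = r, deviance_explained = fit$deviance_explained,
           p_smooth = fit$p_smooth, fit = fit)
    })
  })

  # ---- report ---------------------------------------------------------
  report <- list(
    schema_version = "1.0",
    config = config[!vapply(config, is.null, logical(1))],
    n_trees = nrow(trees), n_cores = length(inputs$cores),
    crossdating = list(n_pass = n_pass, n_series = length(crossdating)),
    chronology_stats = list(
      site = site_stats[c("rbar", "eps", "n_trees", "n_eff")],
      groups = lapply(group_stats, function(s) {
        if (is.null(s)) NULL else s[c("rbar", "eps", "n_trees", "n_eff")]
      }),
      stats_period = stats_period,
      eps_adequate = site_stats$eps > config$eps_threshold),
    pca = list(period = pca_period,
               sdevs = modes$sdevs[1:2],
               var_explained = modes$var_explained[1:2]),
    groups = as.list(table(trees$label)),
    group_taus = lapply(taus, function(t) t[c("tau", "p", "n")]),
    turning_year = loess_site$turning_year,
    trait_fits = lapply(trait_fits, function(f) {
      f[c("slope", "p", "r_squared", "zero_crossing")]
    }),
    damage_thresholds = list(
      tau_zero_damage = thresholds$tau_zero_damage,
      min_damage_significant_negative =
        thresholds$min_damage_significant_negative),
    mean_crown_damage = mean(trees$crown_damage),
    recent_growth = list(
      mean_bai = mean(vapply(recent, `[[`, numeric(1), "mean")),
      by_tree = lapply(recent, function(r) r[c("mean", "cv")])),
    damage_sensitivity = lapply(damage_fits, function(f) {
      list(deviance_explained = f$deviance_explained, p_smooth = f$p_smooth)
    }),
    group_comparison = if (is.null(group_tests)) NULL else {
      lapply(seq_len(nrow(group_tests)), function(i) {
        as.list(group_tests[i, c("trait", "test", "p", "significant")])
      })
    })

  result <- list(report = report, trees = trees,
                 tree_series = tree_series, bai = bai_list,
                 chronologies = list(site_rwi = site_chron_rwi,
                                     site_bai = site_chron_bai,
                                     groups_bai = group_chron),
                 modes = modes, assignment = assignment,
                 tree_trends = tree_trends, trait_fits = trait_fits,
                 climate = climate, sensitivity = sens,
                 damage_fits = damage_fits, truth = truth)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_pipeline_outputs(result, outdir)
  }
  invisible(result)
}

# CSV/JSON exports of the main module outputs
write_pipeline_outputs <- function(result, outdir) {
  wchron <- function(ch, name) {
    utils::write.csv(as.data.frame(ch)[, c("year", "value", "sample_depth")],
                     file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wchron(result$chronologies$site_rwi, "chronology_site_rwi")
  wchron(result$chronologies$site_bai, "chronology_site_bai")
  for (g in names(result$chronologies$groups_bai)) {
    wchron(result$chronologies$groups_bai[[g]],
           paste0("chronology_", tolower(g), "_bai"))
  }
  utils::write.csv(
    result$assignment[, c("tree_id", "label", "r_PC1", "r_PC2")],
    file.path(outdir, "group_assignment.csv"), row.names = FALSE)
  bai_long <- do.call(rbind, lapply(result$bai, function(b) {
    data.frame(tree_id = b$tree_id, year = years(b), bai_mm2 = b$bai)
  }))
  utils::write.csv(bai_long, file.path(outdir, "bai.csv"), row.names = FALSE)
  sens_long <- do.call(rbind, lapply(names(result$sensitivity), function(nm) {
    s <- result$sensitivity[[nm]]
    data.frame(analysis = nm, variable = s$variable, slot = s$labels,
               r = s$r, significant = s$significant)
  }))
  utils::write.csv(sens_long, file.path(outdir, "sensitivity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(outdir)
}
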