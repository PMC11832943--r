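#' Climate departure container
#'
#' Monthly anomalies in standard-deviation units (z-scores) for one
#' variable, possibly averaged over stations.
#'
#' @param variable `"temperature"`, `"precipitation"` or
#'   `"moisture_index"`.
#' @param df data.frame with columns `year`, `month`, `value` and
#'   optionally `n_stations`.
#' @param reference Length-2 reference-period year range.
#' @return data.frame of class `climate_departure`.
#' @export
climate_departure <- function(variable, df, reference) {
  variable <- match.arg(variable,
                        c("temperature", "precipitation", "moisture_index"))
  if (is.null(df$n_stations)) df$n_stations <- 1L
  df <- df[order(df$year, df$month),
           c("year", "month", "value", "n_stations")]
  rownames(df) <- NULL
  structure(df, variable = variable, reference = as.integer(reference),
            class = c("climate_departure", "data.frame"))
}

#' Standardize a station's monthly climate to z-score departures
#'
#' Per calendar month (12 separate climatologies, which removes the
#' seasonal cycle): `z[y, m] = (x[y, m] - mean_m(ref)) / sd_m(ref)`, where
#' mean and sd are taken over the reference period. Over the reference
#' period each month's departures then have mean 0 and sd 1. Values
#' outside the reference period are standardized against the same
#' reference climatology.
#'
#' @param table A [climate_table()].
#' @param reference Length-2 year range (e.g. `c(1992, 2021)`).
#' @param min_ref_years Minimum valid reference years required per month.
#' @return A [climate_departure()].
#' @export
standardize_station <- function(table, reference, min_ref_years = 20L) {
  ref <- table$year >= reference[1] & table$year <= reference[2]
  z <- rep(NA_real_, nrow(table))
  for (m in 1:12) {
    in_m <- table$month == m
    xr <- table$value[ref & in_m]
    xr <- xr[!is.na(xr)]
    if (length(xr) < min_ref_years) {
      stop(sprintf("month %d has only %d reference years (need %d)",
                   m, length(xr), min_ref_years))
    }
    s <- stats::sd(xr)
    if (s == 0) stop("zero reference-period sd for month ", m)
    z[in_m] <- (table$value[in_m] - mean(xr)) / s
  }
  climate_departure(attr(table, "variable"),
                    data.frame(year = table$year, month = table$month,
                               value = z),
                    reference)
}

#' Regional mean of station departures
#'
#' Unweighted mean of the available stations' z-score departures per
#' (year, month); every station series contributes with equal weight, and
#' months missing at some stations are averaged over the remaining ones
#' (no imputation). The per-cell station count is recorded.
#'
#' @param departures List of [climate_departure()] of one variable.
#' @return A [climate_departure()] with `n_stations` per cell.
#' @export
regional_mean <- function(departures) {
  if (length(departures) == 0L) stop("no stations supplied")
  vars <- unique(vapply(departures, attr, character(1), "variable"))
  if (length(vars) != 1L) stop("mixed variables: ", paste(vars, collapse = ", "))
  all_df <- do.call(rbind, lapply(departures, function(d) {
    data.frame(year = d$year, month = d$month, value = d$value)
  }))
  all_df <- all_df[!is.na(all_df$value), ]
  agg <- stats::aggregate(value ~ year + month, all_df, mean)
  cnt <- stats::aggregate(value ~ year + month, all_df, length)
  agg$n_stations <- cnt$value
  climate_departure(vars, agg, attr(departures[[1]], "reference"))
}

#' Moisture index: precipitation minus temperature departure
#'
#' `MI = z_P - z_T` per (year, month), computed on the intersection of the
#' two coverages (with a warning when they differ). Strongly positive
#' values mark cold-wet anomalies, strongly negative values hot-dry ones.
#'
#' @param precip,temp [climate_departure()] of precipitation and
#'   temperature.
#' @return A [climate_departure()] with variable `"moisture_index"`.
#' @export
moisture_index <- function(precip, temp) {
  key_p <- paste(precip$year, precip$month)
  key_t <- paste(temp$year, temp$month)
  common <- intersect(key_p, key_t)
  if (length(common) < length(key_p) || length(common) < length(key_t)) {
    warning("misaligned coverage; moisture index computed on intersection")
  }
  ip <- match(common, key_p)
  it <- match(common, key_t)
  climate_departure(
    "moisture_index",
    data.frame(year = precip$year[ip], month = precip$month[ip],
               value = precip$value[ip] - temp$value[it],
               n_stations = pmin(precip$n_stations[ip],
                                 temp$n_stations[it])),
    attr(precip, "reference"))
}

#' The 19-month climate window of a southern-hemisphere growth year
#'
#' A ring labeled by growth year `y` (the calendar year in which its
#' Oct--Mar growing season ends) integrates climate from the previous
#' growing season's October through the current season's April: October to
#' December of `y - 2`, all of `y - 1`, and January to April of `y` — 19
#' months over 3 calendar years. Slots are labeled `prev.*` (previous
#' growing season Oct--Apr), `win.*` (winter May--Sep) and `curr.*`
#' (current growing season Oct--Apr).
#'
#' @param growth_year Calendar year labeling the ring.
#' @return data.frame with 19 rows: `slot`, `label`, `year`, `month`.
#' @export
season_window <- function(growth_year) {
  y <- as.integer(growth_year)
  months <- c(10:12, 1:12, 1:4)
  yrs <- c(rep(y - 2L, 3), rep(y - 1L, 12), rep(y, 4))
  labels <- c(paste0("prev.", month.abb[c(10:12, 1:4)]),
              paste0("win.", month.abb[5:9]),
              paste0("curr.", month.abb[c(10:12, 1:4)]))
  data.frame(slot = 1:19, label = labels, year = yrs, month = months,
             stringsAsFactors = FALSE)
}

#' Departure values arranged by growth year and season-window slot
#'
#' @param departure A [climate_departure()].
#' @param growth_years Integer vector of growth years.
#' @return Numeric matrix (growth years x 19 slots), `NA` where the
#'   departure has no value.
#' @export
window_matrix <- function(departure, growth_years) {
  key <- paste(departure$year, departure$month)
  out <- matrix(NA_real_, length(growth_years), 19,
                dimnames = list(growth_years, season_window(2000)$label))
  for (i in seq_along(growth_years)) {
    w <- season_window(growth_years[i])
    out[i, ] <- departure$value[match(paste(w$year, w$month), key)]
  }
  out
}
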