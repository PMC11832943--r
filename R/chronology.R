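#' Proportion-of-last-two-years (log) normalization
#'
#' Cross-dating normalization used before computing inter-series
#' correlation and t statistics:
#' `p[t] = ln(2 * w[t] / (w[t] + w[t-1]))`. A constant series maps to 0
#' everywhere; the first year is dropped.
#'
#' @param rings A [ring_series()] with all widths `> 0`.
#' @return An [index_series()] of length `length(rings) - 1`.
#' @export
normalize_p2yrsl <- function(rings) {
  stopifnot(inherits(rings, "ring_series"))
  w <- rings$widths
  if (length(w) < 2L) stop("need at least 2 rings")
  if (any(w <= 0)) stop("zero ring width: log transform undefined")
  p <- log(2 * w[-1] / (w[-1] + w[-length(w)]))
  index_series(rings$series_id, rings$first_year + 1L, p, "p2yrsl")
}

#' Cross-dating validation statistics against a master series
#'
#' Pearson correlation of two normalized series on their common years and
#' the associated Student statistic `t = r * sqrt((n - 2) / (1 - r^2))`.
#' A dating is accepted when `r > 0.32` and `t > 3.5` (both strict).
#'
#' @param series,master [index_series()] (or any objects with [years()] and
#'   [values()]).
#' @param r_min,t_min Acceptance thresholds.
#' @param min_overlap Minimum common years (default 10).
#' @return List with `r`, `t`, `n` and logical `pass`. For `|r| = 1` the t
#'   statistic is reported as the sentinel `1e6`.
#' @export
crossdate_stats <- function(series, master, r_min = 0.32, t_min = 3.5,
                            min_overlap = 10L) {
  common <- intersect(years(series), years(master))
  n <- length(common)
  if (n < min_overlap) {
    stop(sprintf("overlap %d < required %d years", n, min_overlap))
  }
  x <- values(series)[match(common, years(series))]
  y <- values(master)[match(common, years(master))]
  r <- stats::cor(x, y)
  t <- if (1 - r^2 < 1e-12) 1e6 else r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, n = n, pass = (r > r_min) && (t > t_min))
}

# Discrete cubic smoothing (Whittaker-type, 2nd-difference penalty) with the
# dendro frequency-cutoff parameterization: solving
# (I + lambda D'D) g = y, the response to frequency f is
# 1 / (1 + lambda (2 sin(pi f))^4); lambda = (2 sin(pi/nyrs))^-4 puts the
# 50% cutoff at wavelength nyrs.
spline_fit <- function(y, nyrs = 32) {
  n <- length(y)
  if (n < 5L) stop("need at least 5 values for the spline fit")
  lambda <- (2 * sin(pi / nyrs))^-4
  D <- diff(diag(n), differences = 2)
  A <- diag(n) + lambda * crossprod(D)
  as.numeric(solve(A, y))
}

#' Detrend/standardize a ring-width or BAI series
#'
#' Ratio standardization `index[t] = value[t] / fit[t]` with one of two
#' fitted curves: `"spline32"`, a smoothing spline with a 50% frequency
#' cutoff at `nyrs` (default 32) years, which removes age/size trends and
#' low-frequency disturbance effects; or `"mean_line"`, a horizontal line at
#' the series mean, which retains the full low-frequency signal (used for
#' the climate-sensitivity analysis).
#'
#' @param x A [ring_series()] or [bai_series()].
#' @param method `"spline32"` or `"mean_line"`.
#' @param nyrs Spline 50% frequency-cutoff wavelength in years.
#' @return An [index_series()] (dimensionless).
#' @export
detrend <- function(x, method = c("spline32", "mean_line"), nyrs = 32) {
  method <- match.arg(method)
  v <- values(x)
  id <- if (inherits(x, "bai_series")) x$tree_id else x$series_id
  fit <- switch(method,
    mean_line = rep(mean(v), length(v)),
    spline32 = spline_fit(v, nyrs))
  if (any(fit <= 0)) {
    bad <- years(x)[which(fit <= 0)[1]]
    stop("non-positive fitted value in year ", bad)
  }
  index_series(id, x$first_year, v / fit, method)
}

#' Tukey biweight robust mean
#'
#' Iterated biweight location estimate with tuning constant `c = 9` times
#' the MAD; values beyond `c * MAD` of the current center get zero weight.
#' Falls back to the median when the MAD is zero.
#'
#' @param x Numeric values (one year's indices across trees).
#' @param c_tune Tuning constant (default 9).
#' @param iter Iterations (default 10).
#' @return The robust location estimate.
#' @export
biweight_mean <- function(x, c_tune = 9, iter = 10L) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (length(x) == 1L) return(x)
  center <- stats::median(x)
  s <- stats::mad(x, center = center)
  if (s == 0) return(center)
  for (i in seq_len(iter)) {
    u <- (x - center) / (c_tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(center)
    center <- sum(w * x) / sum(w)
  }
  center
}

#' Expressed Population Signal from sample size and Rbar
#'
#' Closed form `EPS = n * rbar / (n * rbar + 1 - rbar)`: how well a finite
#' sample of `n` correlated series (mean inter-series correlation `rbar`)
#' represents the hypothetical population chronology. 0.85 is the
#' conventional adequacy threshold.
#'
#' @param n Number of series (trees).
#' @param rbar Mean inter-series correlation.
#' @return EPS in \[0, 1\] for `rbar >= 0`.
#' @export
eps_from_rbar <- function(n, rbar) n * rbar / (n * rbar + 1 - rbar)

#' Mean inter-series correlation and EPS of a set of index series
#'
#' `rbar` is the mean pairwise Pearson correlation over each pair's common
#' years within `period` (pairs with fewer than `min_overlap` common years
#' are dropped). EPS uses the closed form of [eps_from_rbar()] with `n` the
#' mean per-year number of contributing series over the period.
#'
#' @param indexed List of [index_series()].
#' @param period Length-2 year range.
#' @param min_overlap Minimum pairwise common years (default 30).
#' @return List (class `chronology_stats`) with `rbar`, `eps`, `n_trees`,
#'   `n_eff`, `n_pairs`, `period`.
#' @export
rbar_and_eps <- function(indexed, period, min_overlap = 30L) {
  if (length(indexed) < 2L) stop("need at least 2 series")
  period <- as.integer(period)
  yrs <- period[1]:period[2]
  m <- series_matrix(indexed, yrs)
  cors <- c()
  for (i in seq_len(ncol(m) - 1L)) {
    for (j in (i + 1L):ncol(m)) {
      ok <- stats::complete.cases(m[, c(i, j)])
      if (sum(ok) >= min_overlap) {
        cors <- c(cors, stats::cor(m[ok, i], m[ok, j]))
      }
    }
  }
  if (length(cors) == 0L) {
    stop("no series pair with >= ", min_overlap, " common years in period")
  }
  rbar <- mean(cors)
  n_eff <- mean(rowSums(!is.na(m)))
  structure(
    list(rbar = rbar, eps = eps_from_rbar(n_eff, rbar),
         n_trees = ncol(m), n_eff = n_eff, n_pairs = length(cors),
         period = period),
    class = "chronology_stats")
}

# years x series matrix (NA outside each series' span)
series_matrix <- function(series_list, yrs) {
  m <- matrix(NA_real_, length(yrs), length(series_list))
  colnames(m) <- vapply(series_list, function(s) {
    if (!is.null(s$series_id)) s$series_id else s$tree_id
  }, character(1))
  for (j in seq_along(series_list)) {
    s <- series_list[[j]]
    hit <- intersect(years(s), yrs)
    m[match(hit, yrs), j] <- values(s)[match(hit, years(s))]
  }
  m
}

#' Build a robust-mean chronology from index (or BAI) series
#'
#' Per-year Tukey biweight mean over the series covering that year, with
#' the sample depth recorded. The reliable span starts at the first year
#' with at least `min_depth` contributing series.
#'
#' @param series_list List of [index_series()] or [bai_series()].
#' @param min_depth Sample depth defining the reliable span (default 5).
#' @return A data.frame of class `chronology` with columns `year`, `value`,
#'   `sample_depth`, and attribute `reliable_from`.
#' @export
build_chronology <- function(series_list, min_depth = 5L) {
  if (length(series_list) == 0L) stop("no series supplied")
  yr_range <- range(unlist(lapply(series_list, years)))
  yrs <- yr_range[1]:yr_range[2]
  m <- series_matrix(series_list, yrs)
  value <- apply(m, 1, biweight_mean)
  depth <- rowSums(!is.na(m))
  reliable <- yrs[depth >= min_depth]
  out <- data.frame(year = yrs, value = value, sample_depth = depth)
  structure(out,
            reliable_from = if (length(reliable)) min(reliable) else NA_integer_,
            class = c("chronology", "data.frame"))
}

#' @export
years.chronology <- function(x) x$year

#' @export
values.chronology <- function(x) x$value
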