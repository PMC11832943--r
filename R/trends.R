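#' Mann-Kendall trend test
#'
#' Nonparametric trend test on an annual series: `S` is the sum of signs of
#' all pairwise differences taken in chronological order, and Kendall's
#' `tau` (tau-b, tie-corrected) measures the rank correlation between the
#' values and time. For `n <= 10` with no tied values the two-sided p-value
#' is exact (full null distribution of S); otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param x Annual values, or an object with [values()]/[years()].
#' @param period Optional length-2 year range to restrict an annual series
#'   object to.
#' @return List of class `trend_result`: `tau`, `p`, `s`, `n`, `period`,
#'   `direction_significant` (at `alpha`).
#' @param alpha Significance level for `direction_significant`.
#' @export
mann_kendall <- function(x, period = NULL, alpha = 0.05) {
  if (is.numeric(x)) {
    v <- x
    period <- if (is.null(period)) c(NA_integer_, NA_integer_) else period
  } else {
    yr <- years(x)
    if (is.null(period)) period <- range(yr)
    keep <- yr >= period[1] & yr <= period[2]
    if (!any(keep)) stop("period outside series years")
    v <- values(x)[keep]
  }
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 8L) stop("Mann-Kendall needs n >= 8 (got ", n, ")")
  d <- sign(outer(v, v, `-`))
  s <- sum(d[lower.tri(d)])   # sign(v[i] - v[j]) for i > j
  ties <- table(v)
  ties <- ties[ties > 1L]
  n0 <- n * (n - 1) / 2
  n1 <- sum(ties * (ties - 1) / 2)
  denom <- sqrt((n0 - n1) * n0)
  tau <- if (denom == 0) 0 else s / denom
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (n <= 10L && length(ties) == 0L) {
    p <- kendall_s_exact_p(s, n)
  } else if (var_s == 0) {
    p <- 1
  } else {
    z <- (s - sign(s)) / sqrt(var_s)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, max(p, .Machine$double.xmin))
  }
  structure(
    list(tau = tau, p = p, s = s, n = n, period = period,
         direction_significant = p < alpha),
    class = "trend_result")
}

# Exact two-sided P(|S| >= |s|) for untied data: the null distribution of
# the number of concordance reversals is the Mahonian distribution
# (inversion counts of random permutations), S = n0 - 2k.
kendall_s_exact_p <- function(s, n) {
  counts <- 1
  for (i in 2:n) {
    # convolve with (1 + q + ... + q^(i-1))
    counts <- cumsum_window(c(counts, rep(0, i - 1)), i)
  }
  n0 <- n * (n - 1) / 2
  s_vals <- n0 - 2 * (seq_along(counts) - 1)
  sum(counts[abs(s_vals) >= abs(s)]) / sum(counts)
}

# convolution of a coefficient vector with rep(1, k): c_out[j] = sum of the
# previous k coefficients ending at j
cumsum_window <- function(x, k) {
  cs <- cumsum(x)
  cs - c(rep(0, k), utils::head(cs, -k))
}

#' Regression of per-tree trend strength on a tree trait
#'
#' Ordinary least squares of the trees' Kendall Tau values on one trait
#' (e.g. crown damage in percent). The trait value at which the fitted
#' trend crosses zero (`-intercept/slope`) is reported only when the slope
#' is significant at `p_report`; it is the estimated damage threshold
#' beyond which the growth trend turns negative.
#'
#' @param taus Per-tree Kendall Tau values.
#' @param trait Per-tree trait values (same order).
#' @param trait_name Label for the trait.
#' @param p_report Significance level required to report `zero_crossing`
#'   (default 0.1).
#' @return List of class `trait_trend_fit`: `trait`, `slope`, `intercept`,
#'   `p`, `r_squared`, `zero_crossing` (`NA` when withheld),
#'   `underdetermined` (TRUE for a 2-point fit).
#' @export
trait_trend_regression <- function(taus, trait, trait_name = "trait",
                                   p_report = 0.1) {
  if (length(taus) != length(trait)) stop("length mismatch")
  if (length(taus) < 3L && length(taus) != 2L) stop("need >= 3 trees")
  if (stats::var(trait) == 0) stop("trait has zero variance")
  fit <- stats::lm(taus ~ trait)
  # perfect fits (e.g. the 2-point case) trip summary.lm's warning
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope <- co["trait", "Estimate"]
  p <- if (nrow(co) > 1 && !is.nan(co["trait", "Pr(>|t|)"])) {
    co["trait", "Pr(>|t|)"]
  } else NA_real_
  r2 <- sm$r.squared
  zero <- if (!is.na(p) && p < p_report && slope != 0) {
    -co["(Intercept)", "Estimate"] / slope
  } else if (length(taus) == 2L && slope != 0) {
    -co["(Intercept)", "Estimate"] / slope
  } else NA_real_
  structure(
    list(trait = trait_name, slope = slope,
         intercept = co["(Intercept)", "Estimate"],
         p = p, r_squared = r2, zero_crossing = zero,
         underdetermined = length(taus) == 2L),
    class = "trait_trend_fit")
}

#' Loess smooth of a chronology and its turning year
#'
#' Local quadratic (degree-2) loess of the chronology values on year. The
#' turning year is the year of the global maximum of the smooth, reported
#' only when the smooth ends below that maximum (i.e. growth rose and then
#' declined); a monotone or flat smooth has no turning point.
#'
#' @param chron A `chronology` (or any data.frame with `year`, `value`).
#' @param span Loess span (default 0.75).
#' @return List: `year`, `smoothed`, `turning_year` (or `NA`).
#' @export
loess_trend <- function(chron, span = 0.75) {
  if (nrow(chron) < 20L) stop("need >= 20 years")
  d <- data.frame(year = chron$year, value = chron$value)
  d <- d[!is.na(d$value), ]
  fit <- stats::loess(value ~ year, data = d, span = span, degree = 2)
  sm <- stats::predict(fit, newdata = d)
  i_max <- which.max(sm)
  ends_below <- sm[length(sm)] < max(sm) - 1e-8 * max(abs(sm), 1)
  turning <- if (ends_below) d$year[i_max] else NA_integer_
  list(year = d$year, smoothed = sm, turning_year = turning)
}

#' Crown-damage thresholds for negative growth trends
#'
#' Two damage thresholds derived from the per-tree trend results: (a) the
#' damage at which the fitted Tau-vs-damage regression crosses zero
#' (trend direction flips), and (b) the smallest damage among trees whose
#' own trend is significantly negative.
#'
#' @param trends List of `trend_result` per tree (same order as `damage`).
#' @param damage Per-tree crown damage, percent.
#' @param p_report Passed to [trait_trend_regression()].
#' @return List: `fit` (the `trait_trend_fit`), `tau_zero_damage`,
#'   `min_damage_significant_negative` (`NA` if no such tree).
#' @export
damage_thresholds <- function(trends, damage, p_report = 0.1) {
  taus <- vapply(trends, function(t) t$tau, numeric(1))
  sig_neg <- vapply(trends, function(t) {
    t$direction_significant && t$tau < 0
  }, logical(1))
  fit <- trait_trend_regression(taus, damage, "crown_damage", p_report)
  list(fit = fit,
       tau_zero_damage = fit$zero_crossing,
       min_damage_significant_negative =
         if (any(sig_neg)) min(damage[sig_neg]) else NA_real_)
}
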