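#' Reconstruct basal area increment backwards from DBH
#'
#' Anchors the outermost ring's radius at `dbh / 2` (no bark correction) and
#' steps inward: `r[t-1] = r[t] - w[t]`. The annual basal area increment is
#' `BAI[t] = pi * (r[t]^2 - r[t-1]^2)` (mm^2 yr^-1). Any innermost residual
#' radius (cores that miss the pith) contributes no BAI record. If the
#' cumulative ring widths exceed `dbh / 2` the inner radius is truncated at
#' zero; a mismatch larger than `tol` (as a fraction of `dbh / 2`) is an
#' error. With `rescale = TRUE` the widths are first rescaled
#' proportionally so they sum exactly to `dbh / 2`.
#'
#' @param rings A [ring_series()] of one tree, oldest ring first.
#' @param dbh Diameter at breast height, mm (over bark).
#' @param tol Tolerated fractional mismatch between `sum(widths)` and
#'   `dbh / 2` (default 0.25).
#' @param rescale Rescale widths to sum to `dbh / 2` before reconstruction.
#' @return A [bai_series()] aligned with `rings`.
#' @export
bai_from_dbh <- function(rings, dbh, tol = 0.25, rescale = FALSE) {
  stopifnot(inherits(rings, "ring_series"))
  if (dbh <= 0) stop("dbh must be > 0")
  w <- rings$widths
  half <- dbh / 2
  excess <- sum(w) - half
  if (excess > tol * half) {
    stop(sprintf(
      "cumulative ring widths (%.2f mm) exceed dbh/2 (%.2f mm) by %.1f%%",
      sum(w), half, 100 * excess / half))
  }
  if (rescale) w <- w * half / sum(w)
  # radii outward-anchored: r[n] = dbh/2, r[t-1] = r[t] - w[t]
  r <- half - rev(cumsum(rev(w)))  # r[0..n-1] = radius before each ring
  r <- pmax(c(r, half), 0)         # r has length n+1: inner bound .. outer
  bai <- pi * (r[-1]^2 - r[-length(r)]^2)
  bai_series(rings$tree_id, rings$first_year, bai)
}

#' Hegyi competition index
#'
#' Distance-weighted sum of neighbor-to-target diameter ratios:
#' `CI_i = sum_j (dbh_j / dbh_i) / dist_ij`, with distances in m. When more
#' than `n_max` neighbors are supplied, only the `n_max` nearest enter the
#' sum.
#'
#' @param dbh_i Target tree DBH (any unit, shared with neighbors).
#' @param neighbors data.frame with columns `dbh` and `dist` (m), e.g. the
#'   `neighbors` element of a [read_tree_metadata()] row.
#' @param n_max Number of nearest neighbors retained (default 5).
#' @return Dimensionless competition index.
#' @export
hegyi_index <- function(dbh_i, neighbors, n_max = 5L) {
  if (dbh_i <= 0) stop("target dbh must be > 0")
  if (NROW(neighbors) < 1L) stop("at least one neighbor required")
  if (any(neighbors$dist <= 0)) stop("neighbor distances must be > 0")
  nb <- neighbors[order(neighbors$dist), , drop = FALSE]
  nb <- nb[seq_len(min(n_max, nrow(nb))), , drop = FALSE]
  sum((nb$dbh / dbh_i) / nb$dist)
}

#' Minimum age and mean ring width of a series
#'
#' The ring count at coring height is a minimum age (rotten or missed pith
#' is common in old stems).
#'
#' @param rings A [ring_series()].
#' @return List with `min_age` (ring count) and `mean_rwl` (mm).
#' @export
series_summaries <- function(rings) {
  stopifnot(inherits(rings, "ring_series"))
  list(min_age = length(rings$widths), mean_rwl = mean(rings$widths))
}

#' Recent growth rate and inter-annual variability
#'
#' Mean BAI and its coefficient of variation (sample sd / mean) over a
#' window of years, e.g. the last two decades.
#'
#' @param bai A [bai_series()].
#' @param window Length-2 numeric, first and last year (inclusive).
#' @return List with `mean` (mm^2 yr^-1) and `cv` (dimensionless; `NA` with
#'   a warning when the window mean is 0).
#' @export
recent_growth_stats <- function(bai, window) {
  stopifnot(inherits(bai, "bai_series"), length(window) == 2L)
  sub <- window_series(bai, window[1], window[2])
  m <- mean(sub$bai)
  if (m == 0) {
    warning("window mean BAI is 0; CV undefined")
    return(list(mean = 0, cv = NA_real_))
  }
  list(mean = m, cv = stats::sd(sub$bai) / m)
}
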