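#' Bootstrapped monthly climate-growth correlations
#'
#' Pearson correlation between a standardized chronology and each of the 19
#' season-window monthly departure slots, over `period`. Significance per
#' slot comes from a paired bootstrap: years are resampled with
#' replacement `n_boot` times and a slot is significant when the 95%
#' percentile interval of its bootstrap correlations excludes zero.
#'
#' @param chron A `chronology` (values standardized by the mean-line
#'   method for the climate analysis) or an [index_series()]/[bai_series()].
#' @param departure A [climate_departure()].
#' @param period Length-2 analysis year range.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param conf Bootstrap interval coverage (default 0.95).
#' @return List of class `sensitivity_result`: `variable`, `labels`, `r`
#'   (length 19), `significant` (length 19), `ci` (2 x 19), `n`, `period`.
#' @export
monthly_correlations <- function(chron, departure, period, n_boot = 1000L,
                                 seed, conf = 0.95) {
  if (missing(seed)) stop("seed is required")
  yr <- years(chron)
  keep <- yr >= period[1] & yr <= period[2]
  gy <- yr[keep]
  g <- values(chron)[keep]
  ok <- !is.na(g)
  gy <- gy[ok]; g <- g[ok]
  cm <- window_matrix(departure, gy)
  full <- stats::complete.cases(cm)
  gy <- gy[full]; g <- g[full]; cm <- cm[full, , drop = FALSE]
  n <- length(gy)
  if (n < 30L) stop("overlap ", n, " < 30 years")
  r <- as.numeric(stats::cor(g, cm))
  set.seed(seed)
  boot_r <- matrix(NA_real_, n_boot, 19)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    gb <- g[idx]
    if (stats::sd(gb) == 0) next
    sds <- apply(cm[idx, , drop = FALSE], 2, stats::sd)
    rb <- suppressWarnings(as.numeric(stats::cor(gb, cm[idx, , drop = FALSE])))
    rb[sds == 0] <- NA
    boot_r[b, ] <- rb
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot_r, 2, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  significant <- ci[1, ] > 0 | ci[2, ] < 0
  structure(
    list(variable = attr(departure, "variable"),
         labels = colnames(cm), r = r, significant = significant,
         ci = ci, n = n, period = as.integer(period)),
    class = "sensitivity_result")
}

#' Mean seasonal climate sensitivity of one tree
#'
#' Pearson correlation of a (mean-standardized) tree growth series with
#' each requested season-window slot, averaged arithmetically over the
#' slots — e.g. DJF temperature (`curr.Dec`, `curr.Jan`, `curr.Feb`) or
#' JFM moisture index (`curr.Jan`, `curr.Feb`, `curr.Mar`).
#'
#' @param tree A series object (e.g. mean-standardized BAI
#'   [index_series()]).
#' @param departure A [climate_departure()].
#' @param slots Slot labels (see [season_window()]) or indices in 1..19.
#' @param period Length-2 analysis year range.
#' @return Mean Pearson r across the slots.
#' @export
seasonal_sensitivity <- function(tree, departure, slots, period) {
  yr <- years(tree)
  keep <- yr >= period[1] & yr <= period[2]
  gy <- yr[keep]
  g <- values(tree)[keep]
  cm <- window_matrix(departure, gy)
  if (is.character(slots)) {
    slots <- match(slots, colnames(cm))
    if (anyNA(slots)) stop("unknown slot label")
  }
  cm <- cm[, slots, drop = FALSE]
  full <- stats::complete.cases(cm) & !is.na(g)
  if (sum(full) < 30L) stop("overlap ", sum(full), " < 30 years")
  mean(as.numeric(stats::cor(g[full], cm[full, , drop = FALSE])))
}

#' Generalized additive model of climate sensitivity versus crown damage
#'
#' Penalized-spline GAM (Gaussian family, basis dimension `k`, smoothing
#' parameter by GCV) of the trees' seasonal climate-growth correlation
#' coefficients on crown damage in percent. Reports the fraction of
#' deviance explained (for a Gaussian fit, the analogue of R^2) and the
#' smooth-term p-value, plus the fitted curve on a damage grid.
#'
#' @param per_tree_r Per-tree mean correlation coefficients.
#' @param damage Per-tree crown damage, percent.
#' @param k Spline basis dimension (default 5; sample sizes of ~23 trees
#'   do not support more).
#' @param grid_n Length of the exported damage grid.
#' @return List of class `damage_sensitivity_fit`: `deviance_explained`,
#'   `p_smooth`, `edf`, `grid` (data.frame `damage`, `fit`, `se`), `gam`
#'   (the mgcv fit).
#' @export
damage_sensitivity_fit <- function(per_tree_r, damage, k = 5, grid_n = 100L) {
  if (length(per_tree_r) < 10L) stop("need >= 10 trees")
  if (stats::var(damage) == 0) stop("damage has zero variance")
  if (stats::var(per_tree_r) == 0) {
    # constant response: nothing to explain
    grid <- data.frame(damage = seq(min(damage), max(damage),
                                    length.out = grid_n))
    grid$fit <- rep(per_tree_r[1], grid_n)
    grid$se <- rep(0, grid_n)
    return(structure(
      list(deviance_explained = 0, p_smooth = 1, edf = 0,
           grid = grid, gam = NULL),
      class = "damage_sensitivity_fit"))
  }
  d <- data.frame(r = per_tree_r, damage = damage)
  fit <- mgcv::gam(r ~ s(damage, k = k), data = d, method = "GCV.Cp")
  sm <- summary(fit)
  grid <- data.frame(damage = seq(min(damage), max(damage),
                                  length.out = grid_n))
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE)
  grid$fit <- as.numeric(pr$fit)
  grid$se <- as.numeric(pr$se.fit)
  structure(
    list(deviance_explained = sm$dev.expl,
         p_smooth = unname(sm$s.table[1, "p-value"]),
         edf = unname(sm$s.table[1, "edf"]),
         grid = grid, gam = fit),
    class = "damage_sensitivity_fit")
}
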