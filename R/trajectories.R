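#' Years-by-trees BAI matrix over a common period
#'
#' @param bai_list List of [bai_series()].
#' @param period Length-2 year range; every tree must cover it completely.
#' @return Numeric matrix (rows = years, columns = trees).
#' @export
bai_matrix <- function(bai_list, period) {
  period <- as.integer(period)
  yrs <- period[1]:period[2]
  m <- series_matrix(bai_list, yrs)
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0]
    stop("missing BAI within period for tree(s): ",
         paste(bad, collapse = ", "))
  }
  rownames(m) <- yrs
  m
}

#' Dominant growth modes by PCA of the BAI matrix
#'
#' PCA on the years-by-trees BAI matrix, years as observations and trees as
#' variables, on the correlation matrix (each tree's series standardized):
#' the leading components are common growth trajectories shared by subsets
#' of trees. Component signs are fixed so each component's mean loading is
#' positive.
#'
#' @param m Years-by-trees matrix from [bai_matrix()].
#' @param k Number of retained components (default 2).
#' @return List of class `growth_modes`: `period`, `sdevs`,
#'   `var_explained` (fractions of total variance, all components),
#'   `scores` (years x k), `loadings` (trees x k), `k`.
#' @export
pca_growth_modes <- function(m, k = 2L) {
  if (ncol(m) < k) stop("need at least k trees")
  if (anyNA(m)) stop("missing cells in BAI matrix")
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  flip <- ifelse(colMeans(pc$rotation) < 0, -1, 1)
  scores <- sweep(pc$x, 2, flip, `*`)[, seq_len(k), drop = FALSE]
  loadings <- sweep(pc$rotation, 2, flip, `*`)[, seq_len(k), drop = FALSE]
  yrs <- as.integer(rownames(m))
  structure(
    list(period = range(yrs), sdevs = pc$sdev,
         var_explained = var_explained,
         scores = scores, loadings = loadings, k = k,
         years = yrs),
    class = "growth_modes")
}

#' Assign each tree to the growth mode it correlates most with
#'
#' Each tree's BAI series (over the PCA period) is correlated with each
#' retained component score series; the tree is labeled with the component
#' of largest absolute correlation (signs of components are arbitrary, so
#' magnitude is compared; with the positive-mean-loading sign convention
#' the winning correlations are typically positive). Ties go to the lower
#' component index and are flagged.
#'
#' @param m Years-by-trees matrix from [bai_matrix()] (same period as the
#'   modes).
#' @param modes A `growth_modes` object with `k >= 2`.
#' @return data.frame of class `group_assignment`: `tree_id`, `label`
#'   (`"PC1"`, `"PC2"`, ...), one `r_PCj` column per component, `tied`.
#' @export
assign_to_mode <- function(m, modes) {
  if (modes$k < 2L) stop("need at least 2 retained components")
  r <- stats::cor(m, modes$scores)   # trees x k
  colnames(r) <- paste0("r_PC", seq_len(modes$k))
  a <- abs(r)
  pick <- apply(a, 1, which.max)
  tied <- apply(a, 1, function(z) sum(z == max(z)) > 1L)
  out <- data.frame(tree_id = colnames(m),
                    label = paste0("PC", pick),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(r))
  out$tied <- tied
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Compare tree traits between growth-trajectory groups
#'
#' DBH is compared with the Welch two-sample t-test; the other traits
#' (height, minimum age, crown damage, Hegyi index, mean ring width) with
#' the Mann-Whitney rank-sum test, reflecting their distributions and the
#' unequal group sizes.
#'
#' @param records `tree_records` data.frame containing the trait columns
#'   and a `label` column with exactly two levels.
#' @param traits Character vector of trait column names.
#' @param t_test_traits Traits compared with Welch's t (default `"dbh"`).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per trait: `trait`, `test`, `statistic`,
#'   `p`, `significant`, group means.
#' @export
compare_groups <- function(records,
                           traits = c("dbh", "height", "min_age",
                                      "crown_damage", "hegyi", "mean_rwl"),
                           t_test_traits = "dbh", alpha = 0.05) {
  labs <- unique(records$label)
  if (length(labs) != 2L) stop("need exactly two group labels")
  g1 <- records[records$label == labs[1], , drop = FALSE]
  g2 <- records[records$label == labs[2], , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g2) < 2L) stop("each group needs >= 2 trees")
  rows <- lapply(traits, function(tr) {
    x <- g1[[tr]]; y <- g2[[tr]]
    if (stats::sd(c(x, y)) == 0) {
      # degenerate: no variation at all, trivially no group difference
      return(data.frame(trait = tr, test = "degenerate", statistic = 0,
                        p = 1, significant = FALSE,
                        mean_1 = mean(x), mean_2 = mean(y),
                        stringsAsFactors = FALSE))
    }
    if (tr %in% t_test_traits) {
      ht <- stats::t.test(x, y)   # Welch by default
      test <- "welch_t"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y))
      test <- "mann_whitney"
    }
    data.frame(trait = tr, test = test,
               statistic = unname(ht$statistic), p = ht$p.value,
               significant = ht$p.value < alpha,
               mean_1 = mean(x), mean_2 = mean(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- labs
  out
}
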