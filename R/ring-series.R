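#' Annual ring-width series for one core or tree
#'
#' A `ring_series` holds dated, gap-free annual ring widths (mm) for a single
#' increment core or for the mean series of a tree. Years are implicit:
#' `first_year`, `first_year + 1`, ... Missing (locally absent) rings are
#' encoded as width 0 and flagged; they carry zero basal-area increment.
#'
#' @param series_id Core/series identifier (e.g. `"T01a"`).
#' @param tree_id Tree identifier the core belongs to.
#' @param first_year Calendar year of the earliest ring. Southern-hemisphere
#'   rings spanning October--March are labeled by the calendar year in which
#'   the growing season ends.
#' @param widths Numeric vector of ring widths in mm (0.01 mm resolution
#'   typical). Must be non-negative; zeros are treated as flagged missing
#'   rings.
#' @return An object of class `ring_series`.
#' @examples
#' rs <- ring_series("T01a", "T01", 1900, c(1.2, 0.8, 1.1))
#' years(rs)
#' @export
ring_series <- function(series_id, tree_id, first_year, widths) {
  stopifnot(is.character(series_id), length(series_id) == 1L,
            is.character(tree_id), length(tree_id) == 1L)
  first_year <- as.integer(first_year)
  widths <- as.numeric(widths)
  if (length(widths) < 1L) stop("ring_series needs at least one ring")
  if (anyNA(widths)) stop("ring widths must not contain NA")
  if (any(widths < 0)) stop("ring widths must be >= 0 (0 flags a missing ring)")
  structure(
    list(series_id = series_id, tree_id = tree_id,
         first_year = first_year, widths = widths,
         missing = widths == 0),
    class = "ring_series")
}

#' Annual basal area increment series for one tree
#'
#' @param tree_id Tree identifier.
#' @param first_year Calendar year of the earliest increment.
#' @param bai Numeric vector of annual basal area increments (mm^2 yr^-1),
#'   all `>= 0`.
#' @return An object of class `bai_series`.
#' @export
bai_series <- function(tree_id, first_year, bai) {
  bai <- as.numeric(bai)
  if (length(bai) < 1L) stop("bai_series needs at least one value")
  if (anyNA(bai) || any(bai < 0)) stop("BAI values must be >= 0 and non-NA")
  structure(
    list(tree_id = tree_id, first_year = as.integer(first_year), bai = bai),
    class = "bai_series")
}

#' Calendar years covered by a series
#'
#' @param x A `ring_series`, `bai_series`, or any object with `first_year`
#'   and a value vector.
#' @return Integer vector of consecutive calendar years.
#' @export
years <- function(x) UseMethod("years")

#' @export
years.ring_series <- function(x) x$first_year + seq_along(x$widths) - 1L

#' @export
years.bai_series <- function(x) x$first_year + seq_along(x$bai) - 1L

#' @export
years.index_series <- function(x) x$first_year + seq_along(x$values) - 1L

#' Annual values of a series
#' @param x A series object.
#' @return Numeric vector aligned with [years()].
#' @export
values <- function(x) UseMethod("values")

#' @export
values.ring_series <- function(x) x$widths

#' @export
values.bai_series <- function(x) x$bai

#' @export
values.index_series <- function(x) x$values

#' Dimensionless index series (detrended/standardized growth)
#'
#' @param series_id Identifier carried over from the source series.
#' @param first_year Calendar year of the first index value.
#' @param values Numeric index values.
#' @param method Standardization tag (e.g. `"spline32"`, `"mean_line"`,
#'   `"p2yrsl"`).
#' @return An object of class `index_series`.
#' @export
index_series <- function(series_id, first_year, values, method = "unknown") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("index_series needs at least one value")
  structure(
    list(series_id = series_id, first_year = as.integer(first_year),
         values = values, method = method),
    class = "index_series")
}

#' @export
print.ring_series <- function(x, ...) {
  yr <- years(x)
  cat(sprintf("<ring_series %s (tree %s): %d rings, %d-%d, mean %.3f mm>\n",
              x$series_id, x$tree_id, length(x$widths),
              min(yr), max(yr), mean(x$widths)))
  invisible(x)
}

#' @export
print.bai_series <- function(x, ...) {
  yr <- years(x)
  cat(sprintf("<bai_series %s: %d yr, %d-%d, mean %.1f mm2/yr>\n",
              x$tree_id, length(x$bai), min(yr), max(yr), mean(x$bai)))
  invisible(x)
}

# Subset a series object to a span of years (inclusive); errors if the
# span is not fully covered.
window_series <- function(x, from, to) {
  yr <- years(x)
  if (from < min(yr) || to > max(yr)) {
    stop(sprintf("window %d-%d outside series years %d-%d",
                 from, to, min(yr), max(yr)))
  }
  keep <- yr >= from & yr <= to
  v <- values(x)[keep]
  if (inherits(x, "ring_series")) {
    ring_series(x$series_id, x$tree_id, from, v)
  } else if (inherits(x, "bai_series")) {
    bai_series(x$tree_id, from, v)
  } else {
    index_series(x$series_id, from, v, x$method)
  }
}
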