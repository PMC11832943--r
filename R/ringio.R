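#' Read a Tucson (.rwl) ring-width file
#'
#' Parses the decadal Tucson format used by the ITRDB: each line carries a
#' series id, the calendar year of its first value, and up to ten annual
#' values in 0.01 mm units. The series terminator may be `999` (0.01 mm
#' dialect) or `-9999`. Widths are returned in mm. Zero values are kept as
#' flagged missing rings.
#'
#' @param path Path to a `.rwl` file.
#' @return Named list of [ring_series()], one per series. The `tree_id` is
#'   the series id with a trailing single letter (core suffix a/b/c)
#'   stripped, if present.
#' @export
read_rwl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  acc <- list()   # series_id -> list(first_year, widths, next_year)
  done <- character(0)
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) < 3L) {
      stop(sprintf("malformed decade line %d: '%s'", i, lines[[i]]))
    }
    id <- tok[[1]]
    year <- suppressWarnings(as.integer(tok[[2]]))
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (is.na(year) || anyNA(vals)) {
      stop(sprintf("malformed decade line %d: '%s'", i, lines[[i]]))
    }
    terminated <- FALSE
    last <- vals[length(vals)]
    if (last == 999 || last == -9999) {
      terminated <- TRUE
      vals <- vals[-length(vals)]
    }
    if (id %in% done) {
      stop("overlapping duplicate series id: ", id)
    }
    if (is.null(acc[[id]])) {
      acc[[id]] <- list(first_year = year, widths = numeric(0),
                        next_year = year)
    } else if (year != acc[[id]]$next_year) {
      stop(sprintf(
        "parse error at line %d: series %s jumps from year %d to %d",
        i, id, acc[[id]]$next_year, year))
    }
    acc[[id]]$widths <- c(acc[[id]]$widths, vals / 100)
    acc[[id]]$next_year <- year + length(vals)
    if (terminated) done <- c(done, id)
  }
  open <- setdiff(names(acc), done)
  if (length(open)) {
    warning("series without terminator: ", paste(open, collapse = ", "))
  }
  out <- lapply(names(acc), function(id) {
    ring_series(id, tree_id_from_series(id), acc[[id]]$first_year,
                acc[[id]]$widths)
  })
  names(out) <- names(acc)
  out
}

# "T01a" -> "T01"; ids without a trailing lowercase letter are their own tree.
tree_id_from_series <- function(id) sub("(?<=\\d)[a-z]$", "", id, perl = TRUE)

#' Write ring-width series to a Tucson (.rwl) file
#'
#' Values are written in 0.01 mm units in decadal lines, each series closed
#' by the `999` terminator. [read_rwl()] of the written file round-trips the
#' values to 0.01 mm.
#'
#' @param series List of [ring_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series) {
    yr <- years(s)
    v <- as.integer(round(s$widths * 100))
    i <- 1L
    while (i <= length(v)) {
      y0 <- yr[i]
      # run to the end of the decade
      n_take <- min(10L - (y0 %% 10L), length(v) - i + 1L)
      chunk <- v[i:(i + n_take - 1L)]
      is_last <- (i + n_take - 1L) == length(v)
      line <- sprintf("%-8s%4d%s", s$series_id, y0,
                      paste0(sprintf("%6d", chunk), collapse = ""))
      if (is_last && n_take < 10L) line <- paste0(line, sprintf("%6d", 999L))
      writeLines(line, con)
      if (is_last && n_take == 10L) {
        writeLines(sprintf("%-8s%4d%6d", s$series_id, y0 + 10L, 999L), con)
      }
      i <- i + n_take
    }
  }
  invisible(path)
}

#' Read ring widths from a long-format CSV
#'
#' Accepts the second I/O dialect used for deposited replication tables:
#' one row per (series, year) with columns for series id, year and width in
#' mm. Column names are configurable so a deposited table's schema can be
#' mapped without rewriting the file.
#'
#' @param path CSV path.
#' @param cols Named character vector mapping the roles `series_id`, `year`,
#'   `width_mm` to column names in the file.
#' @return Named list of [ring_series()].
#' @export
read_rings_csv <- function(path,
                           cols = c(series_id = "series_id", year = "year",
                                    width_mm = "width_mm")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unname(cols[c("series_id", "year", "width_mm")])
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- lapply(split(df, df[[cols[["series_id"]]]]), function(d) {
    d <- d[order(d[[cols[["year"]]]]), ]
    yrs <- d[[cols[["year"]]]]
    if (any(diff(yrs) != 1L)) {
      stop("non-consecutive years in series ", d[[cols[["series_id"]]]][1])
    }
    id <- as.character(d[[cols[["series_id"]]]][1])
    ring_series(id, tree_id_from_series(id), yrs[1], d[[cols[["width_mm"]]]])
  })
  out
}

#' Merge the cores of one tree into a mean ring-width series
#'
#' Per calendar year, the arithmetic mean over the cores that cover that
#' year; the merged series spans the union of the cores' year ranges.
#'
#' @param series List of 1--3 [ring_series()] sharing one `tree_id`.
#' @return A [ring_series()] with `series_id = tree_id`.
#' @export
merge_cores_to_tree <- function(series) {
  if (length(series) == 0L) stop("no cores supplied")
  tree <- unique(vapply(series, function(s) s$tree_id, character(1)))
  if (length(tree) != 1L) {
    stop("cores belong to different trees: ", paste(tree, collapse = ", "))
  }
  if (length(series) == 1L) {
    s <- series[[1]]
    return(ring_series(tree, tree, s$first_year, s$widths))
  }
  y0 <- min(vapply(series, function(s) s$first_year, integer(1)))
  y1 <- max(vapply(series, function(s) max(years(s)), integer(1)))
  yrs <- y0:y1
  m <- matrix(NA_real_, length(yrs), length(series))
  for (j in seq_along(series)) {
    s <- series[[j]]
    m[match(years(s), yrs), j] <- s$widths
  }
  if (!any(rowSums(!is.na(m)) == length(series))) {
    stop("cores of tree ", tree, " share no overlapping years")
  }
  ring_series(tree, tree, y0, rowMeans(m, na.rm = TRUE))
}

#' Read a tree metadata table
#'
#' Expected CSV columns: `tree_id`, `dbh_mm`, `height_m`, `crown_damage`
#' (percent, recorded in 5-percent classes), and `neighbors` — a
#' semicolon-separated list of `dbh_mm:dist_m` pairs for the nearest
#' neighboring trees used in the Hegyi competition index. An empty neighbor
#' field yields an empty neighbor table.
#'
#' @param path CSV path.
#' @param cols Optional column-name mapping, as in [read_rings_csv()].
#' @return A data.frame (class `tree_records`) with one row per tree and a
#'   `neighbors` list-column of data.frames with columns `dbh`, `dist`.
#' @export
read_tree_metadata <- function(path,
                               cols = c(tree_id = "tree_id", dbh = "dbh_mm",
                                        height = "height_m",
                                        crown_damage = "crown_damage",
                                        neighbors = "neighbors")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- unname(cols)
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  rec <- data.frame(tree_id = as.character(df[[cols[["tree_id"]]]]),
                    dbh = as.numeric(df[[cols[["dbh"]]]]),
                    height = as.numeric(df[[cols[["height"]]]]),
                    crown_damage = as.numeric(df[[cols[["crown_damage"]]]]),
                    stringsAsFactors = FALSE)
  if (any(rec$dbh <= 0)) stop("validation error: dbh must be > 0")
  bad <- rec$crown_damage < 0 | rec$crown_damage > 100
  if (any(bad)) {
    stop("validation error: crown_damage outside [0,100] for tree ",
         paste(rec$tree_id[bad], collapse = ", "))
  }
  rec$neighbors <- lapply(df[[cols[["neighbors"]]]], parse_neighbors)
  class(rec) <- c("tree_records", "data.frame")
  rec
}

parse_neighbors <- function(s) {
  s <- trimws(if (is.na(s)) "" else as.character(s))
  if (!nzchar(s)) return(data.frame(dbh = numeric(0), dist = numeric(0)))
  parts <- strsplit(strsplit(s, ";")[[1]], ":")
  dbh <- as.numeric(vapply(parts, `[`, character(1), 1))
  dist <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(dbh) || anyNA(dist)) stop("malformed neighbor field: ", s)
  if (any(dist <= 0)) stop("validation error: neighbor distance must be > 0")
  data.frame(dbh = dbh, dist = dist)
}

#' Monthly climate table for one station and variable
#'
#' @param station_id Station identifier.
#' @param variable `"temperature"` (deg C) or `"precipitation"` (mm).
#' @param df data.frame with columns `year`, `month`, `value`.
#' @return A data.frame of class `climate_table` with attributes
#'   `station_id` and `variable`.
#' @export
climate_table <- function(station_id, variable, df) {
  variable <- match.arg(variable, c("temperature", "precipitation"))
  df <- df[, c("year", "month", "value")]
  if (any(df$month < 1 | df$month > 12)) stop("months must be in 1..12")
  if (anyDuplicated(df[, c("year", "month")])) {
    stop("duplicate (year, month) in climate table ", station_id)
  }
  if (variable == "precipitation" && any(df$value < 0, na.rm = TRUE)) {
    stop("validation error: negative precipitation in station ", station_id)
  }
  df <- df[order(df$year, df$month), ]
  rownames(df) <- NULL
  structure(df, station_id = station_id, variable = variable,
            class = c("climate_table", "data.frame"))
}

#' Read monthly station climate tables from a long CSV
#'
#' Expected columns: `station_id`, `variable` (`temperature` or
#' `precipitation`), `year`, `month`, `value` (deg C or mm).
#'
#' @param path CSV path.
#' @return List of [climate_table()], one per (station, variable),
#'   named `"<station_id>.<variable>"`.
#' @export
read_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "variable", "year", "month", "value")
  if (!all(need %in% names(df))) {
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  key <- paste(df$station_id, df$variable, sep = ".")
  out <- lapply(split(df, key), function(d) {
    climate_table(d$station_id[1], d$variable[1],
                  d[, c("year", "month", "value")])
  })
  out
}
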