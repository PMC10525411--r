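#' Load and clean occurrence records
#'
#' Reads a delimited table of point records, drops rows with missing or
#' unparseable coordinates or coordinates outside the WGS84 bounds, and
#' collapses exact duplicate (longitude, latitude) pairs, keeping the first.
#' A cleaning report is attached to the result.
#'
#' @param path Path to a delimited text file.
#' @param dialect Named list mapping the table's column names:
#'   `lon`, `lat` (required), `year`, `country`, `source` (optional).
#' @param sep Field separator (default `,`).
#' @return An `occurrence_table`: a data frame with columns `longitude`,
#'   `latitude`, `year`, `country`, `source`, carrying attributes
#'   `crs = "WGS84"` and `cleaning` (list: `rows_read`, `rows_dropped`,
#'   `duplicates`).
#' @export
load_occurrences <- function(path,
                             dialect = list(lon = "longitude", lat = "latitude",
                                            year = "year", country = "country",
                                            source = "source"),
                             sep = ",") {
  if (!file.exists(path)) stop("cannot read occurrence file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (k in c("lon", "lat"))
    if (is.null(dialect[[k]]) || !dialect[[k]] %in% names(raw))
      stop("dialect does not identify a '", k, "' column present in the file")
  grab <- function(k, default) {
    nm <- dialect[[k]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  tab <- data.frame(
    longitude = suppressWarnings(as.numeric(grab("lon", NA))),
    latitude  = suppressWarnings(as.numeric(grab("lat", NA))),
    year      = suppressWarnings(as.integer(grab("year", NA_integer_))),
    country   = as.character(grab("country", NA_character_)),
    source    = as.character(grab("source", NA_character_)),
    stringsAsFactors = FALSE)
  rows_read <- nrow(tab)
  ok <- is.finite(tab$longitude) & is.finite(tab$latitude) &
    tab$longitude >= -180 & tab$longitude <= 180 &
    tab$latitude >= -90 & tab$latitude <= 90
  dropped <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]
  dup <- duplicated(tab[, c("longitude", "latitude")])
  n_dup <- sum(dup)
  tab <- tab[!dup, , drop = FALSE]
  rownames(tab) <- NULL
  if (nrow(tab) == 0L)
    stop("no valid occurrence records in ", path,
         " (", rows_read, " rows read, all dropped)")
  as_occurrence_table(tab,
                      cleaning = list(rows_read = rows_read,
                                      rows_dropped = dropped,
                                      duplicates = n_dup))
}

#' Construct an occurrence table from a data frame
#'
#' @param df Data frame with at least `longitude` and `latitude`.
#' @param cleaning Optional cleaning-report list.
#' @return An `occurrence_table`.
#' @export
as_occurrence_table <- function(df, cleaning = NULL) {
  stopifnot(all(c("longitude", "latitude") %in% names(df)))
  if (!all(is.finite(df$longitude)) || !all(is.finite(df$latitude)))
    stop("occurrence records must have finite coordinates")
  if (any(df$longitude < -180 | df$longitude > 180 |
          df$latitude < -90 | df$latitude > 90))
    stop("coordinates outside WGS84 bounds")
  for (k in c("year", "country", "source"))
    if (is.null(df[[k]])) df[[k]] <- NA
  df <- as.data.frame(df)[, c("longitude", "latitude", "year", "country", "source")]
  rownames(df) <- NULL
  structure(df, crs = "WGS84", cleaning = cleaning,
            class = c("occurrence_table", "data.frame"))
}

#' @export
print.occurrence_table <- function(x, ...) {
  cl <- attr(x, "cleaning")
  cat(sprintf("<occurrence_table> %d records (CRS %s)\n", nrow(x), attr(x, "crs")))
  if (!is.null(cl))
    cat(sprintf("  cleaning: %d read, %d dropped, %d duplicates collapsed\n",
                cl$rows_read, cl$rows_dropped, cl$duplicates))
  NextMethod()
}

#' Spatially thin occurrence records on a fixed grid
#'
#' Retains at most one record per thinning cell. The kilometre cell size is
#' converted to a fixed angular size (`cell_km / 111.32` degrees) on a grid
#' anchored at (-180, -90); within a cell the first record in input order is
#' kept, so thinning is deterministic and idempotent.
#'
#' @param table An `occurrence_table`.
#' @param cell_km Thinning cell edge length in kilometres (default 5).
#' @return The thinned `occurrence_table`; attribute `thinning` records the
#'   input and output counts and the angular cell size used.
#' @export
thin_occurrences <- function(table, cell_km = 5) {
  stopifnot(inherits(table, "occurrence_table"))
  if (nrow(table) == 0L) stop("cannot thin an empty occurrence table")
  if (!is.finite(cell_km) || cell_km <= 0)
    stop("cell_km must be a positive length")
  cell_deg <- cell_km / 111.32
  ix <- floor((table$longitude + 180) / cell_deg)
  iy <- floor((table$latitude + 90) / cell_deg)
  keep <- !duplicated(paste(ix, iy))
  out <- as_occurrence_table(table[keep, , drop = FALSE],
                             cleaning = attr(table, "cleaning"))
  attr(out, "thinning") <- list(cell_km = cell_km, cell_deg = cell_deg,
                                n_in = nrow(table), n_out = nrow(out))
  out
}

#' Build an invasion timeline from country first records
#'
#' Bins the earliest record year per country into one open-ended
#' pre-interval `(-Inf, pre_edge)` followed by fixed-width half-open
#' intervals `[edge, edge + width)`; the final interval is truncated at
#' `end` and closed there.
#'
#' @param first_records Data frame with columns `country` and `first_year`
#'   (one row per country; duplicated countries keep their earliest year).
#' @param pre_edge Year closing the open pre-interval (default 1970).
#' @param width Interval width in years (default 10).
#' @param end Last year covered (default 2023).
#' @return An `invasion_timeline`: data frame with `interval_start`,
#'   `interval_end`, `new`, `cumulative`.
#' @export
build_timeline <- function(first_records, pre_edge = 1970, width = 10,
                           end = 2023) {
  stopifnot(is.data.frame(first_records),
            all(c("country", "first_year") %in% names(first_records)))
  fr <- first_records
  if (nrow(fr)) {
    bad <- fr$first_year > end
    if (any(bad))
      stop("first_year after timeline end for: ",
           paste(unique(fr$country[bad]), collapse = ", "))
    fr <- fr[order(fr$first_year), , drop = FALSE]
    fr <- fr[!duplicated(fr$country), , drop = FALSE]
  }
  # regular half-open intervals [edge, edge + width); the remainder after
  # the last full interval is absorbed into it, closed at `end` (the
  # study's final category spans 2010-2023)
  starts <- seq(pre_edge, end, by = width)
  starts <- starts[starts + width <= end | starts == pre_edge]
  starts <- c(-Inf, starts)
  ends <- c(starts[-1], end)
  new <- integer(length(starts))
  for (i in seq_along(starts)) {
    lo <- starts[i]; hi <- ends[i]
    inb <- if (i == length(starts)) fr$first_year >= lo & fr$first_year <= hi
           else fr$first_year >= lo & fr$first_year < hi
    new[i] <- sum(inb)
  }
  out <- data.frame(interval_start = starts, interval_end = ends,
                    new = new, cumulative = cumsum(new))
  structure(out, class = c("invasion_timeline", "data.frame"))
}

#' Segment an invasion timeline into lag, spread, and equilibrium phases
#'
#' The lag phase is the maximal prefix of intervals whose per-interval count
#' of newly invaded countries stays below `spread_rate`; the spread phase is
#' the maximal following run at or above it; the remainder is equilibrium.
#' The open-ended pre-interval never enters the rate comparison (it is
#' absorbed into the lag phase).
#'
#' @param timeline An `invasion_timeline` from [build_timeline()].
#' @param spread_rate Minimum newly invaded countries per interval that
#'   qualifies as spread (default 6).
#' @return A `phase_segmentation`: data frame with `phase`
#'   (`lag`/`spread`/`equilibrium`), `start_year`, `end_year`; empty phases
#'   are omitted. The pre-interval start is the sentinel `-Inf`.
#' @export
classify_phases <- function(timeline, spread_rate = 6) {
  stopifnot(inherits(timeline, "invasion_timeline"))
  if (nrow(timeline) < 2L) stop("timeline must have at least 2 intervals")
  cmp <- which(is.finite(timeline$interval_start)) # rate-comparable intervals
  hot <- timeline$new[cmp] >= spread_rate
  first_hot <- if (any(hot)) cmp[which(hot)[1]] else NA_integer_
  if (is.na(first_hot)) {
    lag_rows <- seq_len(nrow(timeline)); spread_rows <- integer(0); eq_rows <- integer(0)
  } else {
    lag_rows <- seq_len(first_hot - 1L)
    # maximal consecutive run at/above the rate
    i <- first_hot
    while (i <= nrow(timeline) && timeline$new[i] >= spread_rate) i <- i + 1L
    spread_rows <- seq.int(first_hot, i - 1L)
    eq_rows <- if (i <= nrow(timeline)) seq.int(i, nrow(timeline)) else integer(0)
  }
  seg <- function(label, rows) {
    if (!length(rows)) return(NULL)
    data.frame(phase = label,
               start_year = timeline$interval_start[rows[1]],
               end_year = timeline$interval_end[rows[length(rows)]])
  }
  out <- rbind(seg("lag", lag_rows), seg("spread", spread_rows),
               seg("equilibrium", eq_rows))
  rownames(out) <- NULL
  structure(out, spread_rate = spread_rate,
            class = c("phase_segmentation", "data.frame"))
}

#' Write timeline and phase outputs
#'
#' @param timeline An `invasion_timeline`.
#' @param phases A `phase_segmentation`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the list written to JSON.
#' @export
write_timeline_report <- function(timeline, phases, csv_path = NULL,
                                  json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(timeline), csv_path, row.names = FALSE)
  rep <- list(
    intervals = as.data.frame(timeline),
    phases = as.data.frame(phases),
    spread_rate = attr(phases, "spread_rate"))
  if (!is.null(json_path))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(rep)
}
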