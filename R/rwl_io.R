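#' Ring-width series and site datasets
#'
#' A `rw_series` holds one measured (or simulated) tree-ring width series:
#' a series id, the id of the site it belongs to, the calendar year of the
#' first ring, and the ordered ring widths in millimetres. Years are
#' consecutive; gaps are rejected rather than imputed because the downstream
#' pipeline assumes gap-free measured series.
#'
#' @param series_id,site_id character scalars.
#' @param first_year integer calendar year of the first ring.
#' @param widths numeric vector of positive ring widths (mm).
#' @return An object of class `rw_series`.
#' @seealso [read_rwl()], [write_rwl()], [site_dataset()]
#' @export
rw_series <- function(series_id, site_id, first_year, widths) {
  stopifnot(is.character(series_id), length(series_id) == 1L, nzchar(series_id),
            is.character(site_id), length(site_id) == 1L)
  first_year <- as.integer(first_year)
  widths <- as.numeric(widths)
  if (length(widths) == 0L) stop("series '", series_id, "': widths are empty")
  if (any(!is.finite(widths))) {
    stop("series '", series_id, "': non-finite ring widths")
  }
  if (any(widths <= 0)) {
    stop("series '", series_id, "': ring widths must be positive")
  }
  structure(list(series_id = series_id, site_id = site_id,
                 first_year = first_year, widths = widths),
            class = "rw_series")
}

#' @export
print.rw_series <- function(x, ...) {
  cat(sprintf("<rw_series> %s (site %s), %d rings, %d-%d\n",
              x$series_id, x$site_id, length(x$widths),
              x$first_year, x$first_year + length(x$widths) - 1L))
  invisible(x)
}

#' @rdname rw_series
#' @param x a `rw_series`.
#' @export
series_years <- function(x) {
  x$first_year + seq_along(x$widths) - 1L
}

#' Bundle the ring-width series of one site
#'
#' @param site_id character scalar.
#' @param series list of [rw_series()] objects, all from `site_id`.
#' @param meta optional named list of contrast attributes, e.g.
#'   `elevation_band` (one of `"low"`, `"medium"`, `"high"`) and `watershed`.
#' @return An object of class `site_dataset`.
#' @export
site_dataset <- function(site_id, series, meta = list()) {
  stopifnot(is.character(site_id), length(site_id) == 1L, is.list(series),
            length(series) >= 1L)
  ok <- vapply(series, function(s) inherits(s, "rw_series") &&
                 identical(s$site_id, site_id), logical(1))
  if (!all(ok)) stop("all series must be rw_series objects with site_id '",
                     site_id, "'")
  structure(list(site_id = site_id, series = series, meta = meta),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  yrs <- range(unlist(lapply(x$series, series_years)))
  cat(sprintf("<site_dataset> %s: %d series, years %d-%d\n",
              x$site_id, length(x$series), yrs[1], yrs[2]))
  invisible(x)
}

#' Group a flat list of series into per-site datasets
#'
#' @param series_list list of [rw_series()].
#' @param meta optional data frame with columns `site_id`, `elevation_band`,
#'   `watershed` as read by [read_site_meta()].
#' @return Named list of [site_dataset()] objects.
#' @export
as_site_datasets <- function(series_list, meta = NULL) {
  sites <- vapply(series_list, `[[`, character(1), "site_id")
  out <- lapply(split(series_list, sites), function(ss) {
    sid <- ss[[1]]$site_id
    m <- list()
    if (!is.null(meta)) {
      row <- meta[meta$site_id == sid, , drop = FALSE]
      if (nrow(row) == 1L) m <- as.list(row[, setdiff(names(row), "site_id"),
                                            drop = FALSE])
    }
    site_dataset(sid, ss, meta = m)
  })
  out[order(names(out))]
}

# sentinel conventions of the two dominant Tucson dialects
.RWL_SENTINELS <- c("999" = 0.01, "-9999" = 0.001)

#' Read a decadal Tucson (RWL) ring-width file
#'
#' Parses the decadal layout: every line carries a series id, the calendar
#' year of the line's first value and up to ten integer values; a series is
#' terminated by the sentinel `999` (values in 1/100 mm) or `-9999` (values
#' in 1/1000 mm). The unit convention is auto-detected per series from its
#' sentinel. Years must be consecutive within a series.
#'
#' @param path path to the RWL file.
#' @param site_id site label attached to all series in the file; defaults to
#'   the file name without extension.
#' @return List of [rw_series()] with widths in millimetres.
#' @export
read_rwl <- function(path, site_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  site_id <- site_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  open <- list()    # id -> list(first_year, values, next_year)
  done <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(tok) < 2L) {
      stop("line ", i, ": expected a series id and a decade year")
    }
    id <- tok[1]
    yr <- suppressWarnings(as.integer(tok[2]))
    if (is.na(yr)) stop("line ", i, ": non-numeric decade year '", tok[2], "'")
    vals_tok <- tok[-(1:2)]
    if (!is.null(done[[id]])) {
      stop("line ", i, ": series '", id, "' reappears after its end marker ",
           "(duplicate years)")
    }
    st <- open[[id]]
    if (is.null(st)) {
      st <- list(first_year = yr, values = numeric(0), next_year = yr)
    } else if (yr != st$next_year) {
      stop("line ", i, ": series '", id, "' expected decade year ",
           st$next_year, " but found ", yr,
           if (yr < st$next_year) " (duplicate year)" else " (gap in years)")
    }
    ended <- FALSE
    for (v in vals_tok) {
      if (v %in% names(.RWL_SENTINELS)) {
        scale <- .RWL_SENTINELS[[v]]
        done[[id]] <- rw_series(id, site_id, st$first_year,
                                st$values * scale)
        open[[id]] <- NULL
        ended <- TRUE
        break
      }
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) stop("line ", i, ": non-numeric value '", v, "'")
      st$values <- c(st$values, num)
      st$next_year <- st$next_year + 1L
    }
    if (!ended) open[[id]] <- st
  }
  if (length(open) > 0L) {
    stop("series without end-of-series marker: ",
         paste(names(open), collapse = ", "))
  }
  if (length(done) == 0L) return(list())
  unname(done[order(names(done))])
}

#' Write ring-width series to a decadal Tucson (RWL) file
#'
#' Emits the `999`-sentinel dialect (values in 1/100 mm): one line per decade
#' with the series id, the year of the first value on the line and up to ten
#' integer values; the sentinel follows the last value. Widths are rounded
#' to 1/100 mm, the dialect's precision.
#'
#' @param series_list list of [rw_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(series_list, path) {
  lines <- character(0)
  for (s in series_list) {
    if (!inherits(s, "rw_series")) stop("series_list must contain rw_series")
    if (any(s$widths <= 0)) stop("series '", s$series_id,
                                 "': non-positive width")
    vals <- as.integer(round(s$widths * 100))
    yrs <- series_years(s)
    tokens <- c(as.character(vals), "999")
    tok_years <- c(yrs, yrs[length(yrs)] + 1L)
    # break lines at decade boundaries
    decade <- tok_years %/% 10L
    for (d in unique(decade)) {
      sel <- decade == d
      lines <- c(lines, paste0(sprintf("%-8s", s$series_id),
                               sprintf("%6d", tok_years[sel][1]),
                               paste0(sprintf("%6s", tokens[sel]),
                                      collapse = "")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write ring-width data in long CSV form
#'
#' The long format has columns `series_id`, `site_id`, `year`, `width` (mm)
#' and is accepted everywhere RWL is; it is the more convenient form for
#' synthetic fixtures.
#'
#' @param path CSV path.
#' @return `read_rw_csv()`: list of [rw_series()]; `write_rw_csv()`: `path`.
#' @export
read_rw_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "site_id", "year", "width")
  if (!all(need %in% names(df))) {
    stop("long CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$series_id), function(d) {
    d <- d[order(d$year), , drop = FALSE]
    if (anyDuplicated(d$year)) {
      stop("series '", d$series_id[1], "': duplicate years")
    }
    if (!all(diff(d$year) == 1L)) {
      stop("series '", d$series_id[1], "': years are not consecutive")
    }
    rw_series(d$series_id[1], d$site_id[1], d$year[1], d$width)
  })
  unname(out[order(names(out))])
}

#' @rdname read_rw_csv
#' @param series_list list of [rw_series()].
#' @export
write_rw_csv <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(series_id = s$series_id, site_id = s$site_id,
               year = series_years(s), width = s$widths)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pool of historical series lengths
#'
#' One integer length per row (single-column CSV or plain text, with or
#' without a header). Lengths below 50 years are dropped with a message,
#' mirroring the convention that historical series shorter than 50 years are
#' not used for crossmatching.
#'
#' @param path file path.
#' @param min_length minimum admissible length in years (default 50).
#' @return Integer vector of class `series_length_pool`.
#' @export
read_length_pool <- function(path, min_length = 50L) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  vals <- suppressWarnings(as.numeric(raw))
  if (length(vals) > 0L && is.na(vals[1])) {  # header row
    vals <- vals[-1]
    raw <- raw[-1]
  }
  if (any(is.na(vals))) {
    stop("non-numeric length at row ", which(is.na(vals))[1])
  }
  length_pool(vals, min_length = min_length)
}

#' @rdname read_length_pool
#' @param lengths numeric vector of series lengths (years).
#' @export
length_pool <- function(lengths, min_length = 50L) {
  lengths <- as.integer(round(lengths))
  dropped <- sum(lengths < min_length)
  if (dropped > 0L) {
    message(dropped, " length(s) below ", min_length, " years dropped")
    lengths <- lengths[lengths >= min_length]
  }
  if (length(lengths) == 0L) {
    stop("length pool is empty after dropping lengths below ",
         min_length, " years")
  }
  structure(lengths, class = "series_length_pool")
}

#' @export
print.series_length_pool <- function(x, ...) {
  cat(sprintf("<series_length_pool> %d lengths, %d-%d years (median %.0f)\n",
              length(x), min(x), max(x), stats::median(unclass(x))))
  invisible(x)
}

#' Read site metadata (contrast attributes)
#'
#' CSV with columns `site_id`, `elevation_band` (one of `low`, `medium`,
#' `high`) and `watershed`.
#'
#' @param path CSV path.
#' @return Data frame with validated columns.
#' @export
read_site_meta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "elevation_band", "watershed")
  if (!all(need %in% names(df))) {
    stop("site metadata must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$elevation_band), c("low", "medium", "high"))
  if (length(bad) > 0L) {
    stop("unknown elevation band(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$site_id)) stop("duplicate site_id in metadata")
  df
}
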