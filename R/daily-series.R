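#' Daily sea-surface-temperature series for one reef cell
#'
#' A `daily_series` holds a dated daily SST record for a single georeferenced
#' grid cell. Dates must be strictly increasing at daily cadence; calendar
#' gaps are represented explicitly as `NA` SST values, never skipped.
#'
#' @param cell_id Character scalar identifying the cell.
#' @param lat,lon Decimal-degree coordinates of the cell centre.
#' @param dates `Date` vector, strictly increasing, daily cadence (gaps are
#'   filled with `NA` SST on construction).
#' @param sst Numeric vector of daily SST in degrees Celsius, same length as
#'   `dates`. Values outside the sanity window (-5, 40) are rejected.
#' @return An object of class `daily_series` with elements `cell_id`, `lat`,
#'   `lon`, `dates` and `sst` (gap-filled to unbroken daily cadence).
#' @examples
#' d <- seq(as.Date("2000-01-01"), as.Date("2000-12-31"), by = "day")
#' x <- daily_series("c1", 7.3, 134.5, d, rep(28, length(d)))
#' range(x$dates)
#' @export
daily_series <- function(cell_id, lat, lon, dates, sst) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  stopifnot(length(dates) == length(sst), length(dates) > 0L)
  if (anyDuplicated(dates)) stop("duplicate dates in daily series")
  o <- order(dates)
  dates <- dates[o]
  sst <- as.numeric(sst)[o]
  bad <- !is.na(sst) & (sst < -5 | sst > 40)
  if (any(bad)) {
    stop(sprintf("SST outside sanity window (-5, 40) C on %s",
                 paste(format(utils::head(dates[bad], 3)), collapse = ", ")))
  }
  # make cadence gaps explicit as NA days
  full <- seq(dates[1L], dates[length(dates)], by = "day")
  if (length(full) != length(dates)) {
    s <- rep(NA_real_, length(full))
    s[match(dates, full)] <- sst
    dates <- full
    sst <- s
  }
  structure(list(cell_id = as.character(cell_id), lat = as.numeric(lat),
                 lon = as.numeric(lon), dates = dates, sst = sst),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf("<daily_series> cell %s (%.3f N, %.3f E): %d days %s..%s, %d missing\n",
              x$cell_id, x$lat, x$lon, length(x$dates),
              format(x$dates[1L]), format(x$dates[length(x$dates)]),
              sum(is.na(x$sst))))
  invisible(x)
}

#' Read per-cell daily SST from long-format CSV
#'
#' Expected columns: `cell_id`, `lat`, `lon`, `date` (ISO-8601), `sst_c`.
#'
#' @param path Path to a CSV file.
#' @return Named list of [daily_series()], one per cell.
#' @export
read_sst_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "lat", "lon", "date", "sst_c")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("SST CSV missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$cell_id), function(g) {
    daily_series(g$cell_id[1L], g$lat[1L], g$lon[1L], as.Date(g$date), g$sst_c)
  })
  out[order(names(out))]
}

#' Write one or more daily series to long-format CSV
#'
#' @param series A [daily_series()] or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sst_csv <- function(series, path) {
  if (inherits(series, "daily_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(cell_id = s$cell_id, lat = s$lat, lon = s$lon,
               date = format(s$dates), sst_c = s$sst)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Map coordinates to grid-cell index under the half-open cell convention
#'
#' A point belongs to the cell whose half-open interval
#' `[west, east) x [south, north)` contains it, on a regular grid of
#' resolution `res` degrees anchored at the origin.
#'
#' @param lat,lon Decimal-degree coordinates (vectors).
#' @param res Grid resolution in degrees (default 0.05, the CoralTemp grid).
#' @return Character key `"<ilon>_<ilat>"` of integer cell indices.
#' @export
grid_cell_key <- function(lat, lon, res = 0.05) {
  # snap to the grid index; tolerate floating representation of exact
  # multiples of res by rounding at 1e-9 degrees
  ix <- floor(round(lon / res, 9))
  iy <- floor(round(lat / res, 9))
  paste0(ix, "_", iy)
}
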