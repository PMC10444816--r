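#' Monthly-mean climatology and maximum of monthly means (MMM)
#'
#' Averages all daily SST values falling in each calendar month across the
#' climatology period and takes the warmest month as the MMM, the reference
#' from which bleaching HotSpots are measured. The default period is
#' 1985--2012. Feb 29 participates in February's mean.
#'
#' @param series A [daily_series()].
#' @param period Integer vector `c(start_year, end_year)` (inclusive).
#' @return Object of class `climatology`: `monthly_means` (12 values, degC),
#'   `mmm` (degC), `period`, `cell_id`.
#' @examples
#' d <- seq(as.Date("1985-01-01"), as.Date("2012-12-31"), by = "day")
#' s <- daily_series("c1", 7.3, 134.5, d, rep(28, length(d)))
#' compute_climatology(s, c(1985, 2012))$mmm
#' @export
compute_climatology <- function(series, period = c(1985L, 2012L)) {
  stopifnot(inherits(series, "daily_series"), length(period) == 2L)
  period <- as.integer(period)
  if (period[2L] < period[1L]) stop("climatology period is empty")
  yrs <- series_years(series$dates)
  if (period[1L] < min(yrs) || period[2L] > max(yrs))
    stop(sprintf("climatology period %d:%d outside data range %d:%d",
                 period[1L], period[2L], min(yrs), max(yrs)))
  inside <- yrs >= period[1L] & yrs <= period[2L]
  mon <- date_ymd(series$dates)$month[inside]
  sst <- series$sst[inside]
  mm <- vapply(1:12, function(m) {
    v <- sst[mon == m]
    v <- v[!is.na(v)]
    if (!length(v))
      stop(sprintf("no SST data for month %s inside climatology period",
                   month.name[m]))
    mean(v)
  }, numeric(1))
  structure(list(monthly_means = mm, mmm = max(mm), period = period,
                 cell_id = series$cell_id),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("<climatology> cell %s, %d-%d: MMM = %.3f C (warmest month %s)\n",
              x$cell_id, x$period[1L], x$period[2L], x$mmm,
              month.abb[which.max(x$monthly_means)]))
  invisible(x)
}

#' Write a climatology summary to JSON
#'
#' @param clim A `climatology` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_climatology_json <- function(clim, path) {
  jsonlite::write_json(
    list(cell_id = clim$cell_id, period = clim$period,
         monthly_means = clim$monthly_means, mmm = clim$mmm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
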