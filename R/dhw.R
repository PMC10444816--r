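#' Daily bleaching HotSpots relative to a (possibly rising) stress baseline
#'
#' `HotSpot_i = max(0, SST_i - (MMM + offset(year_i)))`, the positive daily
#' exceedance of SST above the climatological maximum-of-monthly-means, with
#' the baseline optionally raised by a tolerance-enhancement scenario.
#' Missing SST days propagate to missing hotspots; nothing is imputed.
#'
#' @param series A [daily_series()].
#' @param clim A `climatology` from [compute_climatology()].
#' @param scenario Optional [build_offsets()] scenario; `NULL` means the
#'   standard fixed NOAA baseline (offset 0 in every year).
#' @return Numeric vector of hotspots (degC, >= 0 or `NA`), aligned with
#'   `series$dates`.
#' @export
compute_hotspots <- function(series, clim, scenario = NULL) {
  stopifnot(inherits(series, "daily_series"), inherits(clim, "climatology"))
  yrs <- series_years(series$dates)
  base <- clim$mmm + offset_for_year(scenario, yrs)
  pmax(0, series$sst - base)
}

#' Degree heating weeks from daily hotspots
#'
#' DHW on day i is the sum over the trailing 84-day window (days i-83 .. i)
#' of `hotspot/7`, counting only days whose hotspot is at or above the 1 degC
#' accumulation cutoff (a hotspot of exactly 1.0 accumulates). The first 83
#' days of a record have no full window; their DHW is computed over the
#' truncated available window and flagged as warm-up. A missing hotspot
#' anywhere in a window makes that day's DHW missing.
#'
#' The rolling implementation is O(n): per-day contributions
#' `c_i = hotspot_i` when `hotspot_i >= 1`, else 0, are window-summed via
#' cumulative sums and divided by 7 once at the end.
#'
#' @param hotspots Numeric vector of daily hotspots (degC), e.g. from
#'   [compute_hotspots()].
#' @param window Window length in days (default 84 = 12 weeks).
#' @param cutoff Accumulation cutoff in degC (default 1).
#' @return Numeric vector of DHW in degC-weeks with attribute `warmup`
#'   (logical, `TRUE` for the first `window - 1` days).
#' @examples
#' compute_dhw(c(rep(0, 10), rep(2, 7), rep(0, 80)))[17]  # 7 * 2/7 = 2
#' @export
compute_dhw <- function(hotspots, window = 84L, cutoff = 1) {
  n <- length(hotspots)
  contrib <- ifelse(!is.na(hotspots) & hotspots >= cutoff, hotspots, 0)
  isna <- as.numeric(is.na(hotspots))
  cs <- cumsum(contrib)
  cn <- cumsum(isna)
  lag <- function(x) c(rep(0, min(window, n)), x)[seq_len(n)]
  dhw <- (cs - lag(cs)) / 7
  dhw[(cn - lag(cn)) > 0] <- NA_real_
  attr(dhw, "warmup") <- seq_len(n) < window
  dhw
}

#' DHW series for a cell under a climatology and tolerance scenario
#'
#' Convenience wrapper chaining [compute_hotspots()] and [compute_dhw()].
#'
#' @inheritParams compute_hotspots
#' @param window,cutoff Passed to [compute_dhw()].
#' @return Object of class `dhw_series`: `cell_id`, `lat`, `lon`, `dates`,
#'   `hotspots`, `dhw`, `warmup`, `rate`.
#' @export
dhw_series <- function(series, clim, scenario = NULL, window = 84L, cutoff = 1) {
  hs <- compute_hotspots(series, clim, scenario)
  dhw <- compute_dhw(hs, window = window, cutoff = cutoff)
  structure(list(cell_id = series$cell_id, lat = series$lat, lon = series$lon,
                 dates = series$dates, hotspots = hs,
                 dhw = as.numeric(dhw), warmup = attr(dhw, "warmup"),
                 rate = if (is.null(scenario)) 0 else scenario$rate),
            class = "dhw_series")
}

#' @export
print.dhw_series <- function(x, ...) {
  cat(sprintf("<dhw_series> cell %s, rate %.3f C/decade: max DHW %.2f C-weeks\n",
              x$cell_id, x$rate, max(x$dhw, na.rm = TRUE)))
  invisible(x)
}

#' Annual maximum DHW
#'
#' @param x A `dhw_series`, or a numeric DHW vector (then supply `dates`).
#' @param dates `Date` vector when `x` is numeric.
#' @param skip_warmup Drop the warm-up days (no full 84-day window) before
#'   taking maxima; default `TRUE`.
#' @return Named numeric vector, one maximum per calendar year (`NA` for a
#'   year whose DHW is entirely missing).
#' @export
annual_max_dhw <- function(x, dates = NULL, skip_warmup = TRUE) {
  if (inherits(x, "dhw_series")) {
    dates <- x$dates
    dhw <- x$dhw
    if (skip_warmup) {
      dhw <- dhw[!x$warmup]
      dates <- dates[!x$warmup]
    }
  } else {
    dhw <- as.numeric(x)
    if (is.null(dates)) stop("dates required when x is a plain vector")
    wu <- attr(x, "warmup")
    if (skip_warmup && !is.null(wu)) {
      dhw <- dhw[!wu]
      dates <- dates[!wu]
    }
  }
  yrs <- series_years(dates)
  vapply(split(dhw, yrs), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else max(v)
  }, numeric(1))
}

#' Cross-cell summary of annual maximum DHW
#'
#' Mirrors the usual presentation of reef-system heat stress: per-year mean
#' and range of the annual maxima across cells.
#'
#' @param dhw_list List of `dhw_series` (one per cell).
#' @return `data.frame` with `year`, `mean`, `min`, `max` across cells.
#' @export
summarise_annual_max <- function(dhw_list) {
  per_cell <- lapply(dhw_list, annual_max_dhw)
  yrs <- sort(unique(unlist(lapply(per_cell, names))))
  m <- sapply(per_cell, function(v) v[yrs])
  if (is.null(dim(m))) m <- matrix(m, nrow = length(yrs))
  data.frame(year = as.integer(yrs),
             mean = rowMeans(m, na.rm = TRUE),
             min = apply(m, 1, min, na.rm = TRUE),
             max = apply(m, 1, max, na.rm = TRUE),
             row.names = NULL)
}

#' Write DHW series to long-format CSV
#'
#' @param dhw_list A `dhw_series` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dhw_csv <- function(dhw_list, path) {
  if (inherits(dhw_list, "dhw_series")) dhw_list <- list(dhw_list)
  df <- do.call(rbind, lapply(dhw_list, function(s) {
    data.frame(cell_id = s$cell_id, date = format(s$dates), rate = s$rate,
               hotspot_c = s$hotspots, dhw_cweeks = s$dhw, warmup = s$warmup)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
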