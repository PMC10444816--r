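#' Smoothed day-of-year climatology
#'
#' Day-of-year means over a baseline period on a fixed 365-day grid (Feb 29
#' is folded into day 59 before averaging), then smoothed with a circular
#' centred 31-day running mean to remove daily-scale noise from the annual
#' cycle. This is the climatology used by the delta-method bias correction.
#'
#' @param series A [daily_series()].
#' @param baseline Integer `c(start_year, end_year)`, default 1985--2010.
#' @return Numeric vector of 365 smoothed day-of-year means (degC).
#' @export
smooth_daily_climatology <- function(series, baseline = c(1985L, 2010L)) {
  stopifnot(inherits(series, "daily_series"))
  yrs <- series_years(series$dates)
  if (baseline[1L] < min(yrs) || baseline[2L] > max(yrs))
    stop(sprintf("baseline %d:%d not covered by series (%d:%d)",
                 baseline[1L], baseline[2L], min(yrs), max(yrs)))
  inside <- yrs >= baseline[1L] & yrs <= baseline[2L] & !is.na(series$sst)
  doy <- doy365(series$dates[inside])
  sst <- series$sst[inside]
  raw <- vapply(1:365, function(d) {
    v <- sst[doy == d]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(raw))
    stop("baseline leaves empty day-of-year bins; cannot build climatology")
  circular_running_mean(raw, 31L)
}

# centred running mean of window w on a circular series
circular_running_mean <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  xx <- c(x[(n - half + 1L):n], x, x[1:half])
  out <- stats::filter(xx, rep(1 / w, w), sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Delta-method bias correction of a model SST series
#'
#' Seasonally adjusts a climate-model daily SST series against an
#' observational record over a shared baseline:
#' `adjusted(t) = gcm(t) - clim_gcm(doy(t)) + clim_obs(doy(t))`
#' with 31-day-smoothed day-of-year climatologies from
#' [smooth_daily_climatology()]. Over the baseline the smoothed climatology
#' of the adjusted series equals the observational one by construction.
#'
#' Gregorian and 365-day (no-leap) model calendars are supported; a 360-day
#' calendar cannot be represented as calendar dates and is rejected.
#'
#' @param gcm Model [daily_series()].
#' @param obs Observational [daily_series()] for the same cell.
#' @param baseline Shared baseline years, default 1985--2010.
#' @return A [daily_series()] with adjusted SST on the model's dates.
#' @export
delta_correct <- function(gcm, obs, baseline = c(1985L, 2010L)) {
  check_calendar(gcm)
  clim_g <- smooth_daily_climatology(gcm, baseline)
  clim_o <- smooth_daily_climatology(obs, baseline)
  doy <- doy365(gcm$dates)
  adj <- gcm$sst - clim_g[doy] + clim_o[doy]
  out <- gcm
  out$sst <- adj
  out
}

# a 360-day model calendar shows up as ~5 absent days in (almost) every
# year beyond the Feb 29 gap; reject it rather than guess a day mapping
check_calendar <- function(series) {
  yrs <- series_years(series$dates)
  cnt <- tapply(!is.na(series$sst), yrs, sum)
  cnt <- cnt[cnt >= 300]  # ignore partial years at the record edges
  if (length(cnt) && stats::median(cnt) <= 362)
    stop("series looks like a 360-day model calendar; supply Gregorian or ",
         "365-day (no-leap) daily data")
  invisible(series)
}

#' Bleaching-event years from annual maximum DHW
#'
#' A year counts as a mass-bleaching event when its annual maximum DHW
#' reaches or exceeds the Bleaching Alert Level 2 threshold of 8 degC-weeks.
#'
#' @param annual_max Named numeric vector of per-year maximum DHW.
#' @param threshold Event threshold in degC-weeks (default 8).
#' @return Named logical vector (`NA` where the annual maximum is missing).
#' @export
detect_bleaching_years <- function(annual_max, threshold = 8) {
  annual_max >= threshold
}

#' Decadal high-frequency bleaching flags
#'
#' A year is flagged when at least two bleaching events fall inside the
#' 10-year window centred on it, taken as years y-4 .. y+5. Edge years use
#' the truncated available window; which flags are truncated is reported in
#' the `truncated` attribute.
#'
#' @param events Logical vector of per-year event indicators, in year order.
#' @param min_events Events required inside the window (default 2).
#' @return Logical vector of flags with attribute `truncated`.
#' @examples
#' high_frequency_flags(c(FALSE, TRUE, FALSE, FALSE, TRUE, rep(FALSE, 6)))
#' @export
high_frequency_flags <- function(events, min_events = 2L) {
  n <- length(events)
  ev <- as.numeric(events)
  ev[is.na(ev)] <- 0
  cs <- c(0, cumsum(ev))
  lo <- pmax(1L, seq_len(n) - 4L)
  hi <- pmin(n, seq_len(n) + 5L)
  counts <- cs[hi + 1L] - cs[lo]
  out <- counts >= min_events
  attr(out, "truncated") <- (seq_len(n) - 4L < 1L) | (seq_len(n) + 5L > n)
  out
}

#' Ensemble mean and standard error of bleaching trajectories
#'
#' @param prop Matrix of per-year proportions, years in rows, one column per
#'   GCM (>= 2 for a defined SE).
#' @return `data.frame` with `mean` and `se` per row (`se = sd / sqrt(G)`;
#'   `NA` with a warning for a single GCM).
#' @export
ensemble_trajectory <- function(prop) {
  prop <- as.matrix(prop)
  g <- ncol(prop)
  m <- rowMeans(prop)
  if (g < 2L) {
    warning("single GCM: ensemble SE undefined")
    se <- rep(NA_real_, nrow(prop))
  } else {
    se <- apply(prop, 1, stats::sd) / sqrt(g)
  }
  data.frame(mean = m, se = se)
}

#' Project bleaching trajectories for an ensemble of model SST series
#'
#' For each GCM and cell, computes DHW from the supplied (already
#' bias-corrected) daily SST using the historical observational climatology
#' with the tolerance scenario's offsets continued forward, then annual
#' maximum DHW, bleaching events (>= 8 degC-weeks) and decadal
#' high-frequency flags, and finally the per-year proportion of cells
#' flagged, summarised across GCMs as mean +/- SE.
#'
#' @param gcm_sst Nested list: `gcm_sst[[gcm]][[cell]]` is a
#'   [daily_series()].
#' @param clims List of `climatology` objects, one per cell (observational).
#' @param scenario A [build_offsets()] scenario (or `NULL` for a fixed
#'   baseline).
#' @param ssp Label attached to the output rows.
#' @return Object of class `projection_table`: `cells` (tidy data.frame
#'   `cell_id, year, gcm, ssp, annual_max_dhw, event, hf_flag`) and
#'   `trajectory` (`year, ssp, rate, mean, se` of the flagged proportion).
#' @export
project_bleaching <- function(gcm_sst, clims, scenario = NULL, ssp = "ssp") {
  stopifnot(length(gcm_sst) >= 1L)
  gcms <- names(gcm_sst)
  if (is.null(gcms)) gcms <- paste0("gcm", seq_along(gcm_sst))
  rows <- list()
  prop_by_gcm <- list()
  for (g in seq_along(gcm_sst)) {
    cells <- gcm_sst[[g]]
    flags <- list()
    for (ci in seq_along(cells)) {
      ds <- dhw_series(cells[[ci]], clims[[ci]], scenario)
      am <- annual_max_dhw(ds)
      ev <- detect_bleaching_years(am)
      hf <- high_frequency_flags(ev)
      flags[[ci]] <- hf
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = ds$cell_id, year = as.integer(names(am)), gcm = gcms[g],
        ssp = ssp, annual_max_dhw = unname(am), event = unname(ev),
        hf_flag = as.logical(hf))
    }
    fm <- do.call(cbind, flags)
    prop_by_gcm[[g]] <- rowMeans(fm)
  }
  prop <- do.call(cbind, prop_by_gcm)
  traj <- ensemble_trajectory(prop)
  yrs <- as.integer(rownames(prop) %||% rows[[1L]]$year)
  out <- list(cells = do.call(rbind, rows),
              trajectory = data.frame(year = sort(unique(rows[[1L]]$year)),
                                      ssp = ssp,
                                      rate = if (is.null(scenario)) 0
                                             else scenario$rate,
                                      mean = traj$mean, se = traj$se))
  class(out) <- "projection_table"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.projection_table <- function(x, ...) {
  cat(sprintf("<projection_table> %d cell-years, %d GCM(s), ssp %s, rate %.2f\n",
              nrow(x$cells), length(unique(x$cells$gcm)),
              x$trajectory$ssp[1L], x$trajectory$rate[1L]))
  invisible(x)
}

#' Regrid a coarse field to a fine grid
#'
#' Bilinear interpolation of a regular coarse lat/lon field to arbitrary
#' target points, and nearest-neighbour overlay onto a fine grid; the two
#' operators used to downscale model SST onto the observational grid.
#'
#' @param lon,lat Coarse grid axes (increasing).
#' @param z Matrix `length(lon) x length(lat)` of field values.
#' @param out_lon,out_lat Target coordinates (vectors of equal length).
#' @param method `"bilinear"` or `"nearest"`.
#' @return Numeric vector of interpolated values at the target points.
#' @export
regrid_field <- function(lon, lat, z, out_lon, out_lat,
                         method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(nrow(z) == length(lon), ncol(z) == length(lat))
  if (method == "nearest") {
    i <- vapply(out_lon, function(p) which.min(abs(lon - p)), 0L)
    j <- vapply(out_lat, function(p) which.min(abs(lat - p)), 0L)
    return(z[cbind(i, j)])
  }
  i <- findInterval(out_lon, lon, all.inside = TRUE)
  j <- findInterval(out_lat, lat, all.inside = TRUE)
  tx <- (out_lon - lon[i]) / (lon[i + 1L] - lon[i])
  ty <- (out_lat - lat[j]) / (lat[j + 1L] - lat[j])
  tx <- pmin(pmax(tx, 0), 1)
  ty <- pmin(pmax(ty, 0), 1)
  z[cbind(i, j)] * (1 - tx) * (1 - ty) +
    z[cbind(i + 1L, j)] * tx * (1 - ty) +
    z[cbind(i, j + 1L)] * (1 - tx) * ty +
    z[cbind(i + 1L, j + 1L)] * tx * ty
}
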