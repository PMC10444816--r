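#' Tolerance-enhancement scenario: stepwise annual baseline offsets
#'
#' Builds the per-year offsets added to the MMM stress baseline under a
#' simulated linear increase in coral thermal tolerance. The baseline rises
#' in annual steps of `rate / 10` degC, the first step taken at the boundary
#' into the year after `start_year` (steps occur at the end of each calendar
#' year, when temperatures are at their seasonal low), so
#' `offset(y) = rate * max(0, y - start_year) / 10` and the offset is
#' constant within each calendar year.
#'
#' @param rate Enhancement rate in degC per decade; must be >= 0.
#' @param years Integer vector `c(first_year, last_year)` covered.
#' @param start_year Year in which the baseline starts to rise (default 1988,
#'   the middle of the NOAA climatology baseline period); the offset is 0 for
#'   all years up to and including it.
#' @return Object of class `tolerance_scenario`: `rate`, `start_year`,
#'   `years` (vector of covered years), `offsets` (named per-year degC).
#' @examples
#' sc <- build_offsets(0.1, c(1985, 2020))
#' sc$offsets[["2010"]]  # 22 annual steps of 0.01 C -> 0.22
#' @export
build_offsets <- function(rate, years, start_year = 1988L) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0)
    stop("enhancement rate must be a single non-negative number (degC/decade)")
  stopifnot(length(years) == 2L)
  yy <- seq.int(as.integer(years[1L]), as.integer(years[2L]))
  off <- rate * pmax(0L, yy - as.integer(start_year)) / 10
  names(off) <- yy
  structure(list(rate = rate, start_year = as.integer(start_year),
                 years = yy, offsets = off),
            class = "tolerance_scenario")
}

#' @export
print.tolerance_scenario <- function(x, ...) {
  cat(sprintf("<tolerance_scenario> rate %.3f C/decade from %d; offsets %d..%d (final %.3f C)\n",
              x$rate, x$start_year, x$years[1L], x$years[length(x$years)],
              x$offsets[length(x$offsets)]))
  invisible(x)
}

# per-year offset lookup; years beyond the built range continue the linear
# ramp (used by forward projections), years before it are 0
offset_for_year <- function(scenario, year) {
  if (is.null(scenario)) return(rep(0, length(year)))
  scenario$rate * pmax(0, year - scenario$start_year) / 10
}
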