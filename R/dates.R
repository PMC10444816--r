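# Fast calendar arithmetic on Date vectors (days since 1970-01-01).
# format.Date/POSIXlt conversions are far too slow for per-rate, per-cell
# DHW recomputation, so year/month/day-of-year are derived with the
# standard civil-from-days integer algorithm.

date_ymd <- function(dates) {
  z <- as.integer(dates) + 719468L
  era <- z %/% 146097L
  doe <- z - era * 146097L
  yoe <- (doe - doe %/% 1460L + doe %/% 36524L - doe %/% 146096L) %/% 365L
  y <- yoe + era * 400L
  doy <- doe - (365L * yoe + yoe %/% 4L - yoe %/% 100L)
  mp <- (5L * doy + 2L) %/% 153L
  d <- doy - (153L * mp + 2L) %/% 5L + 1L
  m <- mp + ifelse(mp < 10L, 3L, -9L)
  y <- y + (m <= 2L)
  list(year = y, month = m, day = d)
}

date_year <- function(dates) date_ymd(dates)$year

# ordinal day of year, 1..366
date_doy <- function(dates) {
  y <- date_year(dates)
  f <- function(x) x %/% 4L - x %/% 100L + x %/% 400L
  jan1 <- 365L * (y - 1970L) + f(y - 1L) - f(1969L)
  as.integer(dates) - jan1 + 1L
}

series_years <- function(dates) date_year(dates)

# day-of-year on a fixed 1..365 grid: Feb 29 is folded into day 59 and
# subsequent leap-year days shifted back by one
doy365 <- function(dates) {
  doy <- date_doy(dates)
  leap <- is_leap(date_year(dates))
  adj <- leap & doy >= 60L
  doy[adj] <- doy[adj] - 1L
  doy
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
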